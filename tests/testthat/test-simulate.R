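test_that("without a labeled bolus every pool stays unlabeled", {
  p <- sirm_params(dose_g_per_kg = 0)
  sim <- simulate_pools(p, "brain", c(0, 60, 240))
  lf <- pool_labeled_fractions(sim)
  expect_true(all(lf$labeled_fraction == 0))
  expect_equal(sim$states[[3]]$co2, 0)
})

test_that("pure pyruvate-carboxylase routing carries all three carbons", {
  p <- sirm_params(phi = c(pdh = 0, pc = 1, me = 0))
  state <- sirmtrace:::init_pool_state()
  state$pools$pyruvate <- mid(c(0, 0, 0, 1), fractional = TRUE)
  out <- step_pools(state, plasma_m6 = 0, p, "brain", dt = 0.5)
  w <- p$lambda$brain[["malate"]] * 0.5
  # malate influx is pyruvate padded with one unlabeled carbon: pure m+3
  expect_equal(as.numeric(out$pools$malate), c(1 - w, 0, 0, w, 0),
               tolerance = 1e-12)
})

test_that("pools converge to the fully-labeled fixed point", {
  p <- calibrate_defaults()
  gamma1 <- p$gamma; gamma1$brain <- 1
  p <- sirm_params(gamma = gamma1)
  state <- sirmtrace:::init_pool_state()
  for (i in seq_len(8000)) state <- step_pools(state, 1, p, "brain", 0.5)
  expect_equal(as.numeric(state$pools$pyruvate), c(0, 0, 0, 1),
               tolerance = 1e-3)
  # citrate = OAA (+) acetyl-CoA: mean mass of OAA plus 2
  expect_equal(mean_mass_oracle(state$pools$citrate),
               mean_mass_oracle(state$pools$malate) + 2, tolerance = 1e-3)
})

test_that("every recorded pool MID stays normalized", {
  p <- calibrate_defaults()
  for (tis in c("plasma", "liver", "brain")) {
    sim <- simulate_pools(p, tis, c(15, 120, 240))
    for (st in sim$states) {
      for (pool in st$pools) {
        expect_equal(sum(as.numeric(pool)), 1, tolerance = 1e-9)
        expect_true(all(as.numeric(pool) >= 0))
      }
      expect_gte(st$co2, 0); expect_lte(st$co2, 1)
    }
  }
})

test_that("label onset is monotone up to the plasma m+6 peak", {
  p <- calibrate_defaults()
  t_peak <- log(p$ka / p$ke) / (p$ka - p$ke)
  times <- seq(0, floor(t_peak), 0.5)
  sim <- simulate_pools(p, "brain", times)
  lf <- pool_labeled_fractions(sim, times = times)
  for (m in unique(lf$metabolite_id)) {
    v <- unname(lf$labeled_fraction[lf$metabolite_id == m])
    expect_equal(v[1], 0)
    expect_true(all(diff(v) >= -1e-12), label = paste("monotone onset:", m))
  }
})

test_that("TCA labeling lags glycolysis and malic enzyme makes m+1", {
  p <- calibrate_defaults()
  times <- seq(0, 240, 5)
  sim <- simulate_pools(p, "brain", times)
  lf <- pool_labeled_fractions(sim, c("pyruvate", "citrate"), times)
  peak <- function(m) {
    v <- lf$labeled_fraction[lf$metabolite_id == m]
    times[which.max(v)]
  }
  expect_gte(peak("citrate"), peak("pyruvate"))
  expect_gt(as.numeric(pool_mid(sim, "malate", 120))[2], 0)
  # the malic-enzyme route makes m+1 directly from unlabeled pyruvate and
  # labeled CO2, with no multi-turn convolution involved
  p_me <- sirm_params(phi = c(pdh = 0, pc = 0, me = 1))
  state <- sirmtrace:::init_pool_state()
  state$co2 <- 0.5
  out <- step_pools(state, plasma_m6 = 0, p_me, "brain", dt = 0.5)
  w <- p_me$lambda$brain[["malate"]] * 0.5
  expect_equal(as.numeric(out$pools$malate)[2], 0.5 * w, tolerance = 1e-12)
})

test_that("too-coarse time steps are refused", {
  p <- calibrate_defaults()
  state <- sirmtrace:::init_pool_state()
  expect_error(step_pools(state, 0.5, p, "brain", dt = 10), "unstable step")
  expect_error(simulate_pools(p, "kidney", 15), "unknown tissue")
})

test_that("sample tables have the designed size and are seed-reproducible", {
  p <- sirm_params(n_per_group = 2)
  ref <- central_reference()
  design <- expand.grid(tissue = c("plasma", "brain"), time_min = c(15, 120),
                        stringsAsFactors = FALSE)
  design$n <- 2
  tab <- generate_sample_table(p, design, reference = ref)
  expect_equal(length(unique(tab$sample_id)), 8)
  rows_per_met <- sum(ref$n_tracer_carbons + 1 + 4)
  expect_equal(nrow(tab), 8 * rows_per_met)
  tab2 <- generate_sample_table(p, design, reference = ref)
  expect_identical(tab, tab2)
  p3 <- sirm_params(n_per_group = 2, seed = 99L)
  tab3 <- generate_sample_table(p3, design, reference = ref)
  expect_false(identical(tab$raw_abundance, tab3$raw_abundance))
  expect_error(generate_sample_table(p, data.frame(tissue = "bone",
                                                   time_min = 15, n = 1)),
               "unknown tissue")
})

test_that("noise-free tables round-trip through the correction stage", {
  p <- sirm_params(noise_cv = 0)
  ref <- central_reference()
  design <- data.frame(tissue = "brain", time_min = 120, n = 1)
  tab <- generate_sample_table(p, design, reference = ref)
  corrected <- correct_sample_table(tab, reference = ref)
  sim <- simulate_pools(p, "brain", 120)
  for (m in ref$metabolite_id) {
    got <- corrected$frac[corrected$metabolite_id == m]
    truth <- as.numeric(pool_mid(sim, m, 120))
    expect_lt(max(abs(got - truth)), 1e-6)
  }
})
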