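metabolite_id,n_tracer_carbons,fragment_formula,pathway,central_carbon,panel
glucose,6,C16H40NO5Si3,glycolysis,TRUE,FALSE
gap_3pg,3,C12H31O6Si3,glycolysis,TRUE,TRUE
pyruvate,3,C7H16NO3Si,glycolysis,TRUE,TRUE
lactate,3,C9H22O3Si2,glycolysis,TRUE,TRUE
alanine,3,C9H22NO2Si2,glycolysis,TRUE,TRUE
serine,3,C12H31NO3Si3,amino_acids,TRUE,TRUE
glycine,2,C11H29NO2Si3,amino_acids,TRUE,TRUE
citrate,6,C15H37O6Si3,TCA,TRUE,TRUE
alpha_ketoglutarate,5,C12H29NO5Si2,TCA,TRUE,FALSE
fumarate,4,C10H24O4Si2,TCA,TRUE,TRUE
malate,4,C13H33O5Si3,TCA,TRUE,TRUE
glutamate,5,C14H35NO4Si3,neurotransmitters,TRUE,TRUE
aspartate,4,C13H33NO4Si3,neurotransmitters,TRUE,TRUE
gaba,4,C13H33NO2Si3,neurotransmitters,TRUE,TRUE
pyroglutamate,5,C11H26NO3Si2,neurotransmitters,TRUE,TRUE
valine,5,C11H26NO2Si2,amino_acids,FALSE,FALSE
leucine,6,C15H37NO2Si3,amino_acids,FALSE,FALSE
isoleucine,6,C15H37NO2Si3,amino_acids,FALSE,FALSE
threonine,4,C10H24NO2Si2,amino_acids,FALSE,FALSE
methionine,5,C11H26NO2SSi2,amino_acids,FALSE,FALSE
phenylalanine,9,C18H43NO2Si3,amino_acids,FALSE,FALSE
tyrosine,9,C18H43NO2Si3,amino_acids,FALSE,FALSE
tryptophan,11,C20H47N2O2Si3,amino_acids,FALSE,FALSE
lysine,6,C15H37N2O2Si3,amino_acids,FALSE,FALSE
histidine,6,C15H37N2O2Si3,amino_acids,FALSE,FALSE
arginine,6,C15H37N3O2Si3,amino_acids,FALSE,FALSE
asparagine,4,C10H24N2O2Si2,amino_acids,FALSE,FALSE
glutamine,5,C11H26N2O2Si2,amino_acids,FALSE,FALSE
proline,5,C11H26NO2Si2,amino_acids,FALSE,FALSE
cysteine,3,C9H22NO2SSi2,amino_acids,FALSE,FALSE
ornithine,5,C11H26N2O2Si2,amino_acids,FALSE,FALSE
citrulline,6,C15H37N3O2Si3,amino_acids,FALSE,FALSE
beta_alanine,3,C9H22NO2Si2,amino_acids,FALSE,FALSE
homoserine,4,C10H24NO2Si2,amino_acids,FALSE,FALSE
sarcosine,3,C9H22NO2Si2,amino_acids,FALSE,FALSE
succinate,4,C10H24O4Si2,TCA,FALSE,FALSE
isocitrate,6,C15H37O6Si3,TCA,FALSE,FALSE
aconitate,6,C15H37O6Si3,TCA,FALSE,FALSE
x2_hydroxyglutarate,5,C14H35O5Si3,TCA,FALSE,FALSE
glucose_6_phosphate,6,C16H40NO6PSi3,glycolysis,FALSE,FALSE
fructose_6_phosphate,6,C16H40NO6PSi3,glycolysis,FALSE,FALSE
phosphoenolpyruvate,3,C9H22O6PSi2,glycolysis,FALSE,FALSE
threonate,4,C7H15O4Si,other,FALSE,FALSE
amp,6,C12H28N5O6PSi2,other,FALSE,FALSE
fructose,6,C12H28O6Si2,other,FALSE,FALSE
mannose,6,C12H28O6Si2,other,FALSE,FALSE
galactose,6,C12H28O6Si2,other,FALSE,FALSE
ribose,5,C11H26O5Si2,other,FALSE,FALSE
ribitol,5,C11H26O5Si2,other,FALSE,FALSE
xylose,5,C11H26O5Si2,other,FALSE,FALSE
myo_inositol,6,C12H28O6Si2,other,FALSE,FALSE
glycerol,3,C6H13O3Si,other,FALSE,FALSE
glycerol_3_phosphate,3,C6H13O6PSi,other,FALSE,FALSE
cholesterol,6,C12H28OSi2,other,FALSE,FALSE
urea,1,C4H11N2OSi,other,FALSE,FALSE
uracil,4,C7H15N2O2Si,other,FALSE,FALSE
uridine,6,C12H28N2O6Si2,other,FALSE,FALSE
hypoxanthine,5,C11H26N4OSi2,other,FALSE,FALSE
xanthine,5,C11H26N4O2Si2,other,FALSE,FALSE
inosine,6,C12H28N4O5Si2,other,FALSE,FALSE
adenine,5,C11H26N5Si2,other,FALSE,FALSE
adenosine,6,C12H28N5O4Si2,other,FALSE,FALSE
guanosine,6,C12H28N5O5Si2,other,FALSE,FALSE
creatinine,4,C7H15N3OSi,other,FALSE,FALSE
taurine,2,C5H11NO3SSi,other,FALSE,FALSE
putrescine,4,C7H15N2Si,other,FALSE,FALSE
spermidine,6,C12H28N3Si2,other,FALSE,FALSE
pantothenate,6,C12H28NO5Si2,other,FALSE,FALSE
nicotinamide,6,C12H28N2OSi2,other,FALSE,FALSE
oxalate,2,C5H11O4Si,other,FALSE,FALSE
glycolate,2,C5H11O3Si,other,FALSE,FALSE
glycerate,3,C6H13O4Si,other,FALSE,FALSE
erythritol,4,C7H15O4Si,other,FALSE,FALSE
arabitol,5,C11H26O5Si2,other,FALSE,FALSE
sorbitol,6,C12H28O6Si2,other,FALSE,FALSE
maltose,6,C12H28O6Si2,other,FALSE,FALSE
sucrose,6,C12H28O6Si2,other,FALSE,FALSE
trehalose,6,C12H28O6Si2,other,FALSE,FALSE
palmitate,6,C12H28O2Si2,other,FALSE,FALSE
stearate,6,C12H28O2Si2,other,FALSE,FALSE
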