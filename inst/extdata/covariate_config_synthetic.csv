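name,unit,kind,median,p2_5,p97_5,prevalence,levels,probs,miss_rate,c1,c2,c3,c4,c5,derived,components
age,y,continuous,51.3,23.5,69.0,,,,0,0,0,0.15,0.45,0,0,
sex_male,% male,binary,,,,0.358,,,0,0,0,0,0,0,0,
ethnicity_hispanic,% Hispanic/latino,binary,,,,0.101,,,0.02,0,0,0,0,0,0,
family_history_nafld,% yes,binary,,,,0.080,,,0.15,0,0,0,0,0,0,
family_history_cirrhosis,% yes,binary,,,,0.0936,,,0.15,0,0,0,0.05,0,0,
family_history_diabetes,% yes,binary,,,,0.576,,,0.12,0,0,0.15,0.10,0,0,
smoking_history,,categorical,,,,,never;former;current,0.497;0.300;0.203,0.05,0,0,0,0,0,0,
regular_smoker,% yes,binary,,,,0.795,,,0.10,0,0,0,0,0,0,
diabetes,% yes,binary,,,,0.381,,,0.02,0,0,0.45,0.45,0.10,0,
ascites,% yes,binary,,,,0.0131,,,0.02,0,0,0,0.30,0.10,0,
portal_hypertension,% yes,binary,,,,0.0361,,,0.02,0,0,0.10,0.45,0.20,0,
pcos,% yes,binary,,,,0.0657,,,0.05,0,0,0,0,0,0,
antihyperlipidemic_medication,% yes,binary,,,,0.370,,,0.03,0.10,0,0.10,0.10,0,0,
cardiovascular_medication,% yes,binary,,,,0.534,,,0.03,0,0,0.15,0.30,0,0,
bilirubin_direct,mg/dL,continuous,0.1,0,0.4,,,,0.05,0,0,0.10,0.28,0.10,0,
bilirubin_total,mg/dL,continuous,0.7,0.2,2,,,,0.03,0,0,0.05,0.15,0,0,
alt,U/L,continuous,55.5,16,214,,,,0.03,0.45,0.40,0.35,0.05,0.10,0,
ast,U/L,continuous,40.5,16,144,,,,0.03,0.35,0.40,0.40,0.35,0.15,0,
ast_alt,,continuous,0.77,0.39,1.65,,,,0,0,0,0,0,0,1,ast;alt
alkaline_phosphatase,U/L,continuous,82,44,187,,,,0.03,0,0.10,0.10,0.30,0.10,0,
ggt,U/L,continuous,49,15,317,,,,0.08,0.10,0.35,0.20,0.30,0.15,0,
total_protein,g/dL,continuous,7.2,6.1,8.5,,,,0.03,0,0,0,0,0,0,
albumin,g/dL,continuous,4.2,3.4,5,,,,0.03,0,0,0,-0.15,0,0,
prothrombin_time,sec,continuous,11.7,8.9,14.9,,,,0.10,0,0,0,0.15,0,0,
inr,,continuous,1,0.9,1.3,,,,0.10,0,0,0.10,0.25,0,0,
alpha_fetoprotein,ng/mL,continuous,3.6,1.3,13.2,,,,0.569,0,0,0,0.20,0,0,
triglycerides,mg/dL,continuous,151,52.3,456,,,,0.04,0.15,0,0.20,0,0,0,
total_cholesterol,mg/dL,continuous,190,119,286,,,,0.04,0.25,0.05,0,0.20,0.10,0,
hdl_cholesterol,mg/dL,continuous,42,25,73.8,,,,0.04,-0.10,0,0,0,0,0,
ldl_cholesterol,mg/dL,continuous,116,50,195,,,,0.06,0.10,0,0,0.05,0,0,
serum_glucose,mg/dL,continuous,98,70.2,235,,,,0.03,0,0,0.30,0.25,0.10,0,
serum_insulin,uU/mL,continuous,17.6,4.17,74.1,,,,0.25,0.10,0,0.35,0.30,0,0,
hba1c,%,continuous,5.8,4.7,10.1,,,,0.08,0,0.05,0.40,0.35,0.10,0,
homa_ir,,continuous,4.36,1.02,23.2,,,,0.28,0.10,0,0.40,0.30,0,0,
metabolic_syndrome,% yes,binary,,,,0.734,,,0.05,0.15,0,0.20,0.20,0,0,
hemoglobin,g/dL,continuous,14.2,11.2,17.3,,,,0.03,0,0,0,-0.25,0,0,
hematocrit,%,continuous,42,34.3,50,,,,0.03,0,0,0,-0.25,0,0,
wbc,1e9 cells/L,continuous,6.6,3.8,11.9,,,,0.03,0.05,0,0,-0.10,0,0,
platelet_count,cells/uL,continuous,239000,92000,396500,,,,0.03,-0.15,0,-0.10,-0.45,-0.10,0,
sodium,mEq/L,continuous,140,135,145,,,,0.03,0,0,0,0,0,0,
potassium,mEq/L,continuous,4.1,3.4,4.9,,,,0.03,0,0,0,0,0,0,
chloride,mEq/L,continuous,103,97,109,,,,0.03,0,0,0,0,0,0,
bicarbonate,mEq/L,continuous,27,21,31,,,,0.03,0,0,0,0,0,0,
calcium,mg/dL,continuous,9.4,8.6,10.3,,,,0.03,0,0,0,0,0,0,
phosphate,mg/dL,continuous,3.6,2.5,4.7,,,,0.05,0,0,0,0,0,0,
bun,mg/dL,continuous,13,6,24,,,,0.03,0,0,0,0,0,0,
creatinine,mg/dL,continuous,0.8,0.5,1.3,,,,0.03,0,0,0,0,0,0,
uric_acid,mg/dL,continuous,5.8,3.4,9,,,,0.06,0.10,0,0.10,0.05,0,0,
iron,ug/dL,continuous,86,35,168,,,,0.12,0,0,0,0,0,0,
ferritin,ng/mL,continuous,140,16,898,,,,0.12,0,0.20,0.25,0.05,0.10,0,
tibc,ug/dL,continuous,370,247,520,,,,0.12,0,0,0,0,0,0,
alpha1_antitrypsin,mg/dL,continuous,143,81.9,214,,,,0.15,0,0,0.20,0.15,0.10,0,
ana_positive,% positive,binary,,,,0.241,,,0.15,0,0,0,0.05,0,0,
asma_positive,% positive,binary,,,,0.158,,,0.15,0,0,0,0.10,0,0,
ama_positive,% positive,binary,,,,0.0133,,,0.15,0,0,0,0,0,0,
tsh,uU/mL,continuous,1.75,0.28,5.86,,,,0.20,0,0,0,0,0,0,
weight,kg,continuous,95.0,63,139,,,,0.02,0.10,0,0.10,0.05,0,0,
height,cm,continuous,166,151,188,,,,0.02,0,0,0,0,0,0,
bmi,kg/m2,continuous,33.7,24.8,48.5,,,,0.02,0.15,0,0.20,0.10,0,0,
waist_circumference,cm,continuous,108,85.3,135,,,,0.05,0.15,0,0.25,0.20,0,0,
hip_circumference,cm,continuous,115,95.0,146,,,,0.05,0.10,0,0.15,0.10,0,0,
waist_hip,,continuous,0.94,0.79,1.09,,,,0,0,0,0,0,0,1,waist_circumference;hip_circumference
arm_circumference,cm,continuous,35.6,27.1,46.9,,,,0.08,0.10,0,0.15,0.10,0,0,
skin_fold,mm,continuous,33,10.6,69.8,,,,0.344,0.10,0,0.15,0.05,0,0,
bp_systolic,mmHg,continuous,131,105,163,,,,0.02,0,0,0.10,0.15,0,0,
bp_diastolic,mmHg,continuous,76,56,96.7,,,,0.02,0,0,0.05,0.10,0,0,
pulse,beats/min,continuous,74,53,102,,,,0.02,0,0,0,0,0,0,
respiratory_rate,breaths/min,continuous,17,14,24,,,,0.02,0,0,0,0,0,0,
temperature,centigrade,continuous,36.6,35.7,37.3,,,,0.02,0,0,0,0,0,0,
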