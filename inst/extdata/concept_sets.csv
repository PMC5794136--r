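"concept_id","category"
"SIM_LB","live_birth"
"SIM_SB","stillbirth"
"SIM_AB","abortion"
"SIM_DEL","delivery"
"SIM_ECT","ectopic"
"SIM_MTX","methotrexate"
"SIM_ESURG","ectopic_surgery"
"SIM_EASSOC","ectopic_associated"
"SIM_PRETERM","preterm"
"SIM_GEST","gest_age"
"SIM_LMP","lmp"
"SIM_PCONF","preg_confirmation"
"SIM_ANV","antenatal_visit"
"SIM_COMPL","complication"
"SIM_THREAT","threatened_abortion"
"SIM_AFP","afp"
"SIM_ULS","nuchal_ultrasound"
"SIM_FERT","fertility_dating"
"SIM_AMEN","amenorrhea"
"SIM_CONTRA","contraceptive"
"SIM_URINE","urine_test"
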