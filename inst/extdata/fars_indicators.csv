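id,label,cluster,denominator,orientation,province_total
active_treatment_centers,Active treatment centers,institutional,1000,higher_is_better,56
active_treatment_beds,Active beds at treatment centers,institutional,1000,higher_is_better,43
active_health_centers,Active health centers,institutional,1000,higher_is_better,52
clinical_laboratories,Clinical laboratory centers,institutional,1000,higher_is_better,49
pharmacies,Pharmacy,institutional,1000,higher_is_better,64
radiography_centers,Radiography centers,institutional,1000,higher_is_better,34
rehabilitation_centers,Rehabilitation centers,institutional,1000,higher_is_better,61
urban_health_centers,Urban health centers,institutional,1000,higher_is_better,34
internist,Internist,human_resource,1000,higher_is_better,49
cardiologist,Cardiologist,human_resource,1000,higher_is_better,40
pediatrician,Pediatricians,human_resource,1000,higher_is_better,46
psychiatrist,Psychiatrists,human_resource,1000,higher_is_better,59
dermatologist,Dermatologist,human_resource,1000,higher_is_better,58
general_surgeon,General surgery specialist,human_resource,1000,higher_is_better,40
urologist,Urologists,human_resource,1000,higher_is_better,52
orthopedist,Orthopedist,human_resource,1000,higher_is_better,49
neurologist,Neurologist,human_resource,1000,higher_is_better,46
ent_specialist,ENT specialist,human_resource,1000,higher_is_better,46
ophthalmologist,Eye specialist (ophthalmologist),human_resource,1000,higher_is_better,43
gynecologist,Gynecologist,human_resource,1000,higher_is_better,52
anesthesiologist,Anesthesiologist,human_resource,1000,higher_is_better,55
radiotherapist,Radiotherapist,human_resource,1000,higher_is_better,34
pathologist,Pathologist,human_resource,1000,higher_is_better,62
dentist,Dentist,human_resource,1000,higher_is_better,43
pharmacologist,Pharmacologist,human_resource,1000,higher_is_better,52
paramedical,Paramedical,human_resource,1000,higher_is_better,37
infectious_disease_specialist,Infectious diseases specialist,human_resource,1000,higher_is_better,58
general_practitioner,General practitioner,human_resource,1000,higher_is_better,49
rural_health_houses,Rural active health house,rural_institutional,1000,higher_is_better,61
rural_health_centers,Rural active health center,rural_institutional,1000,higher_is_better,31
village_health_house_coverage,Percentage of villages covered by rural active health house,rural_institutional,1000,higher_is_better,55
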