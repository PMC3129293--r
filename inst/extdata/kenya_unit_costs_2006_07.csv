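stratum,cost_per_outpatient_visit,cost_per_admission,cost_per_bedday
dispensary_public,174,NA,NA
health_centre_public,223,3500,3500
district_hospital_public,518,12970,2186
provincial_hospital_public,434,12953,1885
tertiary_hospital_public,1405,48474,4921
dispensary_health_centre_fbo_ngo,633,2242,4194
district_hospital_fbo_ngo,947,15110,3746
dispensary_health_centre_private,850,5614,11871
district_hospital_private,1592,47491,8300
tertiary_hospital_private,2277,96857,18704
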