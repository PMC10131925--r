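zip,hospital_id,distance_km,drive_minutes,transit_minutes
60608,HOSP_01,4.2,9.5,26.0
60609,HOSP_03,3.1,7.0,21.5
60616,HOSP_01,1.4,4.0,12.0
60632,HOSP_02,5.8,12.5,
60653,HOSP_03,2.0,5.5,15.0
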