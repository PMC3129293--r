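centre_id,name,kind,output_measure,output_count,staff_count,floor_area
ADMIN,Administration,support,none,0,4,80
OPD,Outpatient department,final,outpatient_visits,5000,6,120
WARD,General ward,final,bed_days,3600,10,300
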