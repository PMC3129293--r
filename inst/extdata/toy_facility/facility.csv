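centre_id,cost_unit_id,category,year,amount_ksh,traceability
ADMIN,,staffing,2006/2007,300000,indirect
ADMIN,,other_recurrent,2006/2007,100000,indirect
OPD,,staffing,2006/2007,500000,indirect
OPD,,drugs_supplies,2006/2007,200000,indirect
WARD,,staffing,2006/2007,700000,indirect
WARD,,drugs_supplies,2006/2007,250000,indirect
WARD,,fixed,2006/2007,150000,indirect
,outpatient_visit,drugs_supplies,2006/2007,100000,direct
,bed_day,drugs_supplies,2006/2007,120000,direct
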