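stratum,trustee_group,drugs_supplies,staffing,other_recurrent,fixed,total
community_public,public,398041,233770,0,91992,723803
dispensary_public,public,12927460,24728165,1813250,13616947,53085822
health_centre_public,public,6125265,20227027,1711340,9587565,37651197
district_hospital_public,public,42745105,76685778,13503152,62136920,195070955
provincial_hospital_public,public,5434795,16563988,2361242,4098631,28458656
tertiary_hospital_public,public,9536341,28296419,5281557,4251671,47365988
nursing_home_public,public,206159,456053,47458,142743,852413
dispensary_health_centre_fbo_ngo,fbo_ngo,17067193,10931167,4474100,13846061,46318522
district_hospital_fbo_ngo,fbo_ngo,16619036,19528286,8954498,25072792,70174612
nursing_home_fbo_ngo,fbo_ngo,45077,237802,45778,137972,466629
dispensary_health_centre_private,private,27602561,32701781,7688156,34615153,102607650
district_hospital_private,private,8098325,8729259,3797198,19077125,39701906
tertiary_hospital_private,private,7608513,3203292,3543382,4251671,18606858
nursing_home_other,other,1709668,1460479,929799,781843,4881790
district_administration,administration,99635,8629723,7006815,0,15736173
provincial_administration,administration,0,982387,610011,0,1592398
ministry,administration,0,6138911,25512818,0,31651729
TOTAL,,156223174,259734287,87280555,191709086,694947102
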