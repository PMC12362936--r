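# Default constraint table for synthetic-cohort plan review.
# These limits are package defaults (documented, overridable); they are
# deliberately generic SBRT-style values and are not claimed to be any
# trial protocol's numbers. structure "PTV" applies per prescription
# target; other rows match OAR labels. D_CC parameter is cc; V_GY
# parameter is Gy; HIGH_DOSE_SPILLAGE_PCT parameter is the hot threshold
# as % of prescription. margin_override widens the minor band (in the
# limit's units) where the protocol grading is a distinct choice:
# PTV coverage >= 95% of the target at prescription dose, major below 90%.
structure,metric,parameter,limit,limit_sense,tolerance_type,margin_override
PTV,COVERAGE_PCT,NA,95,min,volume_pct,5
PTV,R50,NA,4.5,max,volume_pct,NA
PTV,D2CM_PCT,NA,60,max,volume_pct,NA
PTV,HIGH_DOSE_SPILLAGE_PCT,105,15,max,volume_pct,NA
small_bowel,DMAX,NA,35,max,dose_gy,NA
small_bowel,D_CC,120,20,max,dose_gy,NA
duodenum,DMAX,NA,35,max,dose_gy,NA
duodenum,D_CC,10,25,max,dose_gy,NA
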