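# Reference fixture: PTV dosimetry deviations recorded in the plan review
# (phase 2) of the 10-center dummy-run exercise, one row per deviation.
# Grades not flagged as major in the source table are recorded as minor.
# Multi-target R50/D2cm exemptions were already applied in the review, so
# exempted deviations do not appear here (exempted = FALSE throughout).
# Denominators for rate tallies come from centers.csv. Test input.
case_id,target_or_oar_label,center_id,metric,grade,exempted
Case1,PTV1,B,COVERAGE_PCT,MINOR,FALSE
Case1,PTV1,L,COVERAGE_PCT,MINOR,FALSE
Case1,PTV1,M,COVERAGE_PCT,MINOR,FALSE
Case2,PTV1,B,COVERAGE_PCT,MINOR,FALSE
Case2,PTV1,B,R50,MINOR,FALSE
Case2,PTV1,B,D2CM_PCT,MINOR,FALSE
Case2,PTV1,C,R50,MAJOR,FALSE
Case2,PTV1,C,D2CM_PCT,MAJOR,FALSE
Case2,PTV1,E,HIGH_DOSE_SPILLAGE_PCT,MINOR,FALSE
Case2,PTV1,E,R50,MINOR,FALSE
Case2,PTV1,E,D2CM_PCT,MINOR,FALSE
Case2,PTV1,H,R50,MINOR,FALSE
Case2,PTV1,H,D2CM_PCT,MINOR,FALSE
Case2,PTV1,I,R50,MINOR,FALSE
Case2,PTV1,I,D2CM_PCT,MINOR,FALSE
Case2,PTV1,K,R50,MINOR,FALSE
Case2,PTV1,L,COVERAGE_PCT,MINOR,FALSE
Case2,PTV1,L,R50,MINOR,FALSE
Case2,PTV2,B,COVERAGE_PCT,MINOR,FALSE
Case2,PTV3,B,COVERAGE_PCT,MINOR,FALSE
Case2,PTV3,B,R50,MINOR,FALSE
Case2,PTV3,C,R50,MAJOR,FALSE
Case2,PTV3,E,R50,MINOR,FALSE
Case2,PTV3,H,R50,MINOR,FALSE
Case3,PTV1,B,COVERAGE_PCT,MINOR,FALSE
Case3,PTV1,B,R50,MINOR,FALSE
Case3,PTV1,E,R50,MINOR,FALSE
Case3,PTV1,K,D2CM_PCT,MAJOR,FALSE
Case4,PTV1,A,COVERAGE_PCT,MINOR,FALSE
Case4,PTV1,B,COVERAGE_PCT,MINOR,FALSE
Case4,PTV1,B,R50,MINOR,FALSE
Case4,PTV1,B,D2CM_PCT,MINOR,FALSE
Case4,PTV1,I,D2CM_PCT,MINOR,FALSE
Case4,PTV2,B,COVERAGE_PCT,MINOR,FALSE
Case4,PTV2,B,R50,MINOR,FALSE
Case4,PTV3,A,COVERAGE_PCT,MINOR,FALSE
Case4,PTV3,A,R50,MINOR,FALSE
Case4,PTV3,B,COVERAGE_PCT,MINOR,FALSE
Case4,PTV3,B,R50,MINOR,FALSE
Case4,PTV3,E,COVERAGE_PCT,MINOR,FALSE
Case4,PTV3,E,R50,MINOR,FALSE
Case4,PTV3,F,COVERAGE_PCT,MAJOR,FALSE
Case4,PTV3,H,COVERAGE_PCT,MINOR,FALSE
Case4,PTV3,H,R50,MINOR,FALSE
Case4,PTV3,I,R50,MINOR,FALSE
Case4,PTV3,I,D2CM_PCT,MAJOR,FALSE
Case4,PTV3,K,COVERAGE_PCT,MINOR,FALSE
Case4,PTV3,K,R50,MINOR,FALSE
Case4,PTV3,M,R50,MINOR,FALSE
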