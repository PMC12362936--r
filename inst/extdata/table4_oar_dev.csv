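# Reference fixture: organ-at-risk constraint deviations recorded in the
# plan review (phase 2) of the 10-center dummy-run exercise, one row per
# deviation. Grades not flagged in the source table are recorded as minor.
# One Case4/PTV2 cell was not printed for center I; no row is stored for
# it (tallies use explicit denominators from centers.csv). Test input.
case_id,target_or_oar_label,center_id,metric,grade,exempted
Case1,small_bowel,A,DMAX,MINOR,FALSE
Case1,small_bowel,C,DMAX,MINOR,FALSE
Case1,small_bowel,E,DMAX,MINOR,FALSE
Case1,duodenum,K,DMAX,MINOR,FALSE
Case1,duodenum,K,D_10cc,MINOR,FALSE
Case1,small_bowel,L,DMAX,MAJOR,FALSE
Case4,small_bowel,K,DMAX,MAJOR,FALSE
Case4,small_bowel,B,D_120cc,MAJOR,FALSE
Case4,small_bowel,C,DMAX,MAJOR,FALSE
Case4,small_bowel,C,D_120cc,MAJOR,FALSE
Case4,small_bowel,F,DMAX,MINOR,FALSE
Case4,small_bowel,F,D_120cc,MAJOR,FALSE
Case4,small_bowel,K,DMAX,MAJOR,FALSE
Case4,small_bowel,K,D_120cc,MAJOR,FALSE
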