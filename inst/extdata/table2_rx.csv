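# Reference fixture: dose prescriptions per participating center for each
# case and target volume (total dose in Gy, fraction count), from the same
# 10-center dummy-run exercise (phase 2; center M is the coordinating
# center). shared_plan = 1 flags doses prescribed in a single plan for
# multiple target volumes; the per-volume numbers are stored as printed
# and not de-duplicated. Centers without a separate entry for a target
# have no row. Test input, not package output.
case_id,target_label,volume_cc,center_id,total_dose_gy,fractions,shared_plan
Case1,PTV1,165,A,45,10,0
Case1,PTV1,165,B,35,10,0
Case1,PTV1,165,C,40,10,0
Case1,PTV1,165,E,40,10,0
Case1,PTV1,165,F,40,10,0
Case1,PTV1,165,H,35,10,0
Case1,PTV1,165,I,40,10,0
Case1,PTV1,165,K,30,5,0
Case1,PTV1,165,L,40,10,0
Case1,PTV1,165,M,35,10,0
Case2,PTV1,3,A,40,5,0
Case2,PTV1,3,B,30,3,0
Case2,PTV1,3,C,33,3,0
Case2,PTV1,3,E,35,5,0
Case2,PTV1,3,F,30,3,0
Case2,PTV1,3,H,35,5,0
Case2,PTV1,3,I,30,3,1
Case2,PTV1,3,K,30,3,1
Case2,PTV1,3,L,30,3,0
Case2,PTV1,3,M,40,5,0
Case2,PTV2,10.5,A,40,5,0
Case2,PTV2,10.5,B,35,5,0
Case2,PTV2,10.5,C,33,3,0
Case2,PTV2,10.5,E,35,5,0
Case2,PTV2,10.5,F,30,3,0
Case2,PTV2,10.5,H,35,5,0
Case2,PTV2,10.5,L,30,3,0
Case2,PTV2,10.5,M,40,5,0
Case2,PTV3,7.5,A,40,5,0
Case2,PTV3,7.5,B,30,3,0
Case2,PTV3,7.5,C,33,3,0
Case2,PTV3,7.5,E,35,5,0
Case2,PTV3,7.5,F,30,3,0
Case2,PTV3,7.5,H,35,5,0
Case2,PTV3,7.5,L,30,3,0
Case2,PTV3,7.5,M,40,5,0
Case3,PTV1,49,A,40,5,0
Case3,PTV1,49,B,35,5,0
Case3,PTV1,49,C,35,5,0
Case3,PTV1,49,E,35,5,0
Case3,PTV1,49,F,35,5,0
Case3,PTV1,49,H,27,3,0
Case3,PTV1,49,I,35,5,0
Case3,PTV1,49,K,35,5,0
Case3,PTV1,49,L,30,3,0
Case3,PTV1,49,M,24,3,0
Case4,PTV1,16,A,35,10,0
Case4,PTV1,16,B,40,10,0
Case4,PTV1,16,C,40,10,0
Case4,PTV1,16,E,40,10,0
Case4,PTV1,16,F,40,10,0
Case4,PTV1,16,H,35,10,0
Case4,PTV1,16,I,40,10,1
Case4,PTV1,16,K,30,5,1
Case4,PTV1,16,L,40,10,0
Case4,PTV1,16,M,24,3,0
Case4,PTV2,16,A,35,10,0
Case4,PTV2,16,B,40,10,0
Case4,PTV2,16,C,40,10,0
Case4,PTV2,16,E,35,10,0
Case4,PTV2,16,F,40,10,0
Case4,PTV2,16,H,35,10,0
Case4,PTV2,16,L,40,10,0
Case4,PTV2,16,M,24,3,0
Case4,PTV3,544,A,35,10,0
Case4,PTV3,544,B,40,10,0
Case4,PTV3,544,C,40,10,0
Case4,PTV3,544,E,35,10,0
Case4,PTV3,544,F,40,10,0
Case4,PTV3,544,H,35,10,0
Case4,PTV3,544,I,35,10,0
Case4,PTV3,544,K,25,5,0
Case4,PTV3,544,L,37,10,0
Case4,PTV3,544,M,35,10,0
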