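roi_a,roi_b,r_autism,r_control,z_published,direction
POPE.R,PSTC.R,-0.45,0.43,4.61,decreased
PORB.R,PSTC.R,-0.37,0.47,4.37,decreased
PTRI.R,PSTC.R,-0.48,0.35,4.28,decreased
IT.L,CMF.R,-0.62,0.17,4.38,decreased
IT.L,SF.L,-0.59,0.21,4.33,decreased
IT.L,SF.R,-0.76,0.08,5.21,decreased
IT.L,PARC.R,-0.59,0.22,4.36,decreased
IT.L,RMF.L,-0.63,0.10,4.06,decreased
RAC.L,RMF.R,-0.62,0.26,4.81,decreased
MT.L,SMAR.L,-0.02,0.71,4.38,decreased
MT.R,SMAR.L,-0.17,0.61,4.30,decreased
MT.R,SMAR.R,-0.30,0.61,4.99,decreased
LOCC.L,LING.R,-0.26,0.55,4.27,decreased
LOCC.R,LING.R,-0.25,0.56,4.33,decreased
CMF.L,PTRI.R,0.45,-0.51,-5.05,increased
PARC.R,RMF.R,0.63,-0.53,-6.48,increased
PORB.R,SF.R,0.51,-0.34,-4.46,increased
PTRI.R,SF.R,0.61,-0.32,-5.07,increased
PARC.R,PTRI.R,0.54,-0.32,-4.52,increased
IT.L,FUSI.L,0.81,0.28,-4.11,increased
IT.L,IT.R,0.80,0.00,-5.27,increased
IT.R,RAC.L,0.60,-0.26,-4.66,increased
MT.R,RAC.L,0.52,-0.30,-4.34,increased
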