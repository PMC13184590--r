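# Default species table: 16 EPA priority PAHs plus 6 nitro-/dinitro-PAH degradation
# products with known toxic equivalency quotients (TEQs).
# Provenance / assumptions (all values overridable per run via a user table):
#   teq          : Nisbet-LaGoy toxic equivalency factors for the 16 parents (BAP = 1 by
#                  definition of the reference compound); OEHHA / comparative-potency style
#                  values for the nitrated products. 1,8-dinitropyrene carries 0.9 so that
#                  BAP is the unique TEQ = 1 reference. The choice of the 6 products is a
#                  documented assumption (parent linkage in the 'parent' column).
#   k_oh         : gas-phase OH rate constants, cm3 molecule-1 s-1, literature-typical.
#   k_no3        : EFFECTIVE first-order-in-NO3 constants, cm3 molecule-1 s-1; the true NAP
#                  nitration channel is termolecular in NO2, folded in here.
#   gamma_o3     : heterogeneous O3 reactive-uptake parameter (dimensionless), used as
#                  k_het = gamma_o3 * c_het * [O3 ppb] with configurable c_het.
#   pplfer_l     : partitioning descriptor 1, numerically the log10 octanol-air partition
#                  coefficient at 298.15 K (dimensionless solute size/cavity term).
#   pplfer_s     : partitioning descriptor 2, a polarity/polarizability term.
# Products carry zero kinetic/partitioning parameters: their concentrations are diagnosed
# from the parent fields, not integrated.
abbreviation,full_name,ring_count,species_class,parent,molecular_weight,teq,k_oh,k_no3,gamma_o3,pplfer_l,pplfer_s
NAP,naphthalene,2,parent,,128.17,0.001,2.3e-11,3.0e-13,1.0e-6,5.19,0.92
ACY,acenaphthylene,3,parent,,152.19,0.001,1.1e-10,5.0e-13,2.0e-6,6.34,1.14
ACE,acenaphthene,3,parent,,154.21,0.001,1.0e-10,4.6e-13,2.0e-6,6.52,1.05
FLO,fluorene,3,parent,,166.22,0.001,1.3e-11,3.5e-13,5.0e-6,6.90,1.06
PHEN,phenanthrene,3,parent,,178.23,0.001,2.7e-11,1.2e-13,1.0e-5,7.57,1.29
ANT,anthracene,3,parent,,178.23,0.01,1.3e-10,1.7e-13,1.0e-5,7.71,1.34
FLA,fluoranthene,4,parent,,202.25,0.001,1.1e-11,5.1e-13,5.0e-5,8.76,1.53
PYR,pyrene,4,parent,,202.25,0.001,5.0e-11,2.0e-12,5.0e-5,8.81,1.71
BAA,benzo[a]anthracene,4,parent,,228.29,0.1,5.0e-11,1.0e-12,2.0e-4,10.28,1.70
CHR,chrysene,4,parent,,228.29,0.01,5.0e-11,1.0e-12,2.0e-4,10.30,1.73
BBF,benzo[b]fluoranthene,5,parent,,252.31,0.1,5.0e-11,8.0e-13,5.0e-4,11.34,1.82
BKF,benzo[k]fluoranthene,5,parent,,252.31,0.1,5.0e-11,8.0e-13,5.0e-4,11.37,1.91
BAP,benzo[a]pyrene,5,parent,,252.31,1.0,5.0e-11,9.0e-13,5.0e-4,11.56,1.96
BGHIP,benzo[g.h.i]perylene,6,parent,,276.33,0.01,5.0e-11,7.0e-13,1.0e-3,12.55,1.90
ICDP,indeno[1.2.3-c.d]pyrene,6,parent,,276.33,0.1,5.0e-11,7.0e-13,1.0e-3,12.43,1.93
DAHA,dibenz[a.h]anthracene,5,parent,,278.35,5.0,5.0e-11,7.0e-13,1.0e-3,12.59,2.04
NPYR1,1-nitropyrene,4,NPAH,PYR,247.25,0.1,0,0,0,0,0
NPYR4,4-nitropyrene,4,NPAH,PYR,247.25,0.1,0,0,0,0,0
NCHR6,6-nitrochrysene,4,NPAH,CHR,273.29,10,0,0,0,0,0
NFLO2,2-nitrofluorene,3,NPAH,FLO,211.22,0.01,0,0,0,0,0
DNPYR16,1.6-dinitropyrene,4,DNPAH,PYR,292.25,10,0,0,0,0,0
DNPYR18,1.8-dinitropyrene,4,DNPAH,PYR,292.25,0.9,0,0,0,0,0
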