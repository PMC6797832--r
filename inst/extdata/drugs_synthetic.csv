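# unit: nM
# Synthetic compound pharmacology table. These are NOT measured drug
# parameters: they are invented records spanning realistic pharmacology
# ranges, used to exercise drug-table IO, block translation and
# KDE population seeding.
name,EFTPC,IC50_INa,h_INa,IC50_INaL,h_INaL,IC50_Ito,h_Ito,IC50_IKs,h_IKs,IC50_ICaL,h_ICaL,IC50_IK1,h_IK1,Kmax,IC50h,h_herg,Ku,Vhalf,risk,split
syn_herg_pure,2,200000,1,150000,1,300000,1,400000,1,250000,1,500000,1,40,60,0.9,0.00018,-1,high,training
syn_herg_trap,5,90000,1.1,60000,1,120000,0.9,200000,1,80000,1.2,300000,1,8,25,1,0.00005,-150,high,training
syn_multichannel,30,4000,1.3,900,1,15000,1,30000,1,1100,1.1,60000,1,6,900,0.8,0.1,-90,high,validation
syn_balanced,100,9000,1,2500,1.2,20000,1,35000,1,1400,1,45000,1,3.5,2600,1,0.02,-60,intermediate,training
syn_mixed_kblock,60,30000,1,9000,1,4000,1.4,6000,1,7000,1,9000,1.1,2.5,1500,1.1,0.3,-120,intermediate,training
syn_weak_herg,250,20000,1,12000,1,50000,1,90000,1,5000,0.9,110000,1,1.2,9000,1,0.8,-180,intermediate,validation
syn_late_na,400,15000,1.2,1800,1,80000,1,120000,1,30000,1,200000,1,1.5,16000,1,0.5,-40,intermediate,validation
syn_cal_block,45,60000,1,40000,1,90000,1,150000,1,300,1.3,250000,1,0.8,20000,1,0.9,-170,low,training
syn_na_block,900,1200,1.5,2500,1,70000,1,110000,1,25000,1,160000,1,0.5,45000,1,0.6,-140,low,training
syn_clean,150,80000,1,50000,1,150000,1,250000,1,60000,1,400000,1,0.3,90000,1,0.95,-190,low,validation
syn_cal_na,70,5000,1,3000,1.1,100000,1,200000,1,800,1.2,300000,1,0.6,30000,1,0.7,-100,low,validation
syn_ikr_fast,12,100000,1,80000,1,150000,1,60000,1,90000,1,200000,1,5,300,1,0.9,-30,high,validation
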