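drug,th_ead_c1,th_ead_c2,qnet,apd90,peakca,risk,split
Ibutilide,22.25,19.375,7.17,734,227,high,validation
Quinidine,15.62,28.12,20.80,775,206,high,training
Bepridil,87.625,84.25,44.59,424,229,high,training
Vandetanib,89.75,90.875,48.82,432,215,high,validation
Azimilide,85.625,89.125,49.03,409,242,high,validation
Dofetilide,87.5,88.87,51.83,376,242,high,training
Sotalol,89.375,90.0,56.05,363,248,high,training
Metoprolol,91.00,90.5,56.48,352,281,low,validation
Domperidone,99.625,99.625,59.91,382,163,intermediate,validation
Terfenadine,91.25,89.125,59.99,382,230,intermediate,training
Cisapride,89.75,86.5,60.28,332,243,intermediate,training
Droperidol,91.25,90.5,61.89,326,245,intermediate,validation
Ondansetron,91.00,91.125,62.10,340,238,intermediate,training
Pimozide,92.75,89.625,62.14,334,215,intermediate,validation
Astemizole,92.00,92.125,62.97,318,243,intermediate,validation
Chlorpromazine,92.25,92.75,65.93,316,238,intermediate,training
Clozapine,93.375,93.5,67.55,303,234,intermediate,validation
Tamoxifen,93.5,93.5,69.41,294,234,low,validation
Clarithromycin,94.00,93.875,69.56,302,220,intermediate,validation
Risperidone,93.75,93.5,70.23,290,232,intermediate,validation
Loratadine,93.75,93.75,70.44,289,233,low,validation
Disopyramide,95.000,95.0,72.64,288,213,high,validation
Ranolazine,90.125,86.875,74.23,348,253,low,training
Verapamil,99.25,99.125,74.85,320,157,low,training
Nitrendipine,98.5,98.5,79.00,276,178,low,validation
Nifedipine,NoEAD,98.5,87.77,261,142,low,validation
Diltiazem,NoEAD,NoEAD,92.05,257,130,low,training
Mexiletine,97.625,94.75,92.26,304,200,low,training
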