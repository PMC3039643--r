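# Published genotype-frequency tables for Anopheles gambiae M/S diagnostic
# markers in samples from The Gambia (Mandina Ba = MB, Sare Samba Sowe = SR,
# Wellingara = WE, 2006) and Guinea Bissau (Antula district of Bissau City,
# A-1995 / A-1996 / A-2007).  Only frequencies and sample sizes N were
# published; integer genotype counts are reconstructed by largest-remainder
# apportionment (see counts_from_frequencies).
#
# genotype order for single-locus tables: MM, MS, SS
# joint-genotype column order (X-locus genotype / 3L genotype):
#   MM/MM, SS/SS, MS/MS, MM/MS, MM/SS, MS/MM, MS/SS, SS/MS, SS/MM
study: Anopheles gambiae M/S diagnostic genotype frequencies, far-western range
genotype_order: [MM, MS, SS]
joint_order: [MM/MM, SS/SS, MS/MS, MM/MS, MM/SS, MS/MM, MS/SS, SS/MS, SS/MM]
sine_x:
  - {sample: MB, country: The Gambia, year: 2006, "N": 101, freq: [0.57, 0.03, 0.40]}
  - {sample: SR, country: The Gambia, year: 2006, "N": 153, freq: [0.54, 0.01, 0.44]}
  - {sample: WE, country: The Gambia, year: 2006, "N": 50, freq: [1.00, 0.00, 0.00]}
  - {sample: A-1995, country: Guinea Bissau, year: 1995, "N": 100, freq: [0.28, 0.22, 0.50]}
  - {sample: A-1996, country: Guinea Bissau, year: 1996, "N": 79, freq: [0.43, 0.25, 0.32]}
  - {sample: A-2007, country: Guinea Bissau, year: 2007, "N": 153, freq: [0.08, 0.22, 0.69],
     flag: published summary statistics for this row are internally inconsistent
       with its genotype frequencies; excluded from reproduction checks}
locus_3l:
  - {sample: MB, country: The Gambia, year: 2006, "N": 97, freq: [0.54, 0.15, 0.31]}
  - {sample: SR, country: The Gambia, year: 2006, "N": 151, freq: [0.57, 0.20, 0.23]}
  - {sample: WE, country: The Gambia, year: 2006, "N": 44, freq: [0.52, 0.48, 0.00]}
  - {sample: A-1995, country: Guinea Bissau, year: 1995, "N": 99, freq: [0.67, 0.28, 0.05]}
  - {sample: A-1996, country: Guinea Bissau, year: 1996, "N": 78, freq: [0.60, 0.24, 0.15]}
  - {sample: A-2007, country: Guinea Bissau, year: 2007, "N": 145, freq: [0.37, 0.31, 0.32]}
joint_x_3l:
  - {sample: MB, country: The Gambia, year: 2006, "N": 97,
     freq: [0.515, 0.309, 0.010, 0.052, 0, 0.010, 0.000, 0.093, 0.010]}
  - {sample: SR, country: The Gambia, year: 2006, "N": 151,
     freq: [0.510, 0.225, 0.007, 0.033, 0, 0, 0.007, 0.159, 0.060]}
  - {sample: WE, country: The Gambia, year: 2006, "N": 44,
     freq: [0.523, 0, 0, 0.477, 0, 0, 0, 0, 0]}
  - {sample: Tot, country: The Gambia, year: 2006, "N": 292,
     freq: [0.514, 0.219, 0.007, 0.106, 0, 0.003, 0.003, 0.113, 0.034]}
  - {sample: A-1995, country: Guinea Bissau, year: 1995, "N": 99,
     freq: [0.263, 0.030, 0.040, 0.020, 0, 0.152, 0.020, 0.222, 0.253]}
  - {sample: A-1996, country: Guinea Bissau, year: 1996, "N": 78,
     freq: [0.397, 0.090, 0.115, 0.013, 0.026, 0.103, 0.038, 0.115, 0.103]}
  - {sample: A-2007, country: Guinea Bissau, year: 2007, "N": 144,
     freq: [0.042, 0.243, 0.069, 0.014, 0.021, 0.090, 0.056, 0.229, 0.236]}
  - {sample: Tot, country: Guinea Bissau, year: 0, "N": 321,
     freq: [0.196, 0.140, 0.072, 0.016, 0.016, 0.112, 0.040, 0.199, 0.209]}
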