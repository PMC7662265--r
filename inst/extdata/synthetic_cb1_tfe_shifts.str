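data_shifts

loop_
  _Atom_chem_shift.ID
  _Atom_chem_shift.Seq_ID
  _Atom_chem_shift.Comp_ID
  _Atom_chem_shift.Atom_ID
  _Atom_chem_shift.Val
  1 391 THR HA 4.3729
  2 391 THR H 8.1380
  3 391 THR CA 61.7306
  4 392 VAL HA 4.1159
  5 392 VAL H 8.0203
  6 392 VAL CA 62.1053
  7 393 ASN HA 4.7475
  8 393 ASN H 8.3988
  9 393 ASN CA 53.1153
  10 394 PRO HA 4.2001
  11 394 PRO CA 65.2577
  12 395 ILE HA 3.9554
  13 395 ILE H 8.0228
  14 395 ILE CA 63.0544
  15 396 ILE HA 3.9472
  16 396 ILE H 8.0047
  17 396 ILE CA 62.9326
  18 397 TYR HA 4.3051
  19 397 TYR H 8.1200
  20 397 TYR CA 59.9208
  21 398 ALA HA 4.0866
  22 398 ALA H 8.2471
  23 398 ALA CA 54.5526
  24 399 LEU HA 4.0843
  25 399 LEU H 8.1727
  26 399 LEU CA 57.0404
  27 400 ARG HA 4.1057
  28 400 ARG H 8.2359
  29 400 ARG CA 57.8237
  30 401 SER HA 4.2254
  31 401 SER H 8.3013
  32 401 SER CA 60.2939
  33 402 LYS HA 4.0793
  34 402 LYS H 8.2892
  35 402 LYS CA 58.0800
  36 403 ASP HA 4.6344
  37 403 ASP H 8.3500
  38 403 ASP CA 54.0895
  39 404 LEU HA 4.1943
  40 404 LEU H 8.1631
  41 404 LEU CA 56.3689
  42 405 ARG HA 4.1887
  43 405 ARG H 8.2271
  44 405 ARG CA 57.0158
  45 406 HIS HA 4.5818
  46 406 HIS H 8.4160
  47 406 HIS CA 56.2821
  48 407 ALA HA 4.1816
  49 407 ALA H 8.2410
  50 407 ALA CA 53.7401
  51 408 PHE HA 4.4731
  52 408 PHE H 8.2999
  53 408 PHE CA 58.8837
  54 409 ARG HA 4.3571
  55 409 ARG H 8.2372
  56 409 ARG CA 56.0481
stop_
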