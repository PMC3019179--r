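{
  "r01_kcat": 1,
  "r01_Km": 200,
  "r02_Vmax": 10,
  "r02_Km": 20,
  "r03_k": 0.05,
  "r04_kcat": 1,
  "r04_Km": 200,
  "r05_Vmax": 27.23,
  "r05_Km": 3,
  "r06_k": 0.3,
  "r07_k": 0.3,
  "r08_kcat": 2,
  "r08_Km": 200,
  "r09_Vmax": 6.438,
  "r09_Km": 1,
  "r10_kcat": 1,
  "r10_Km": 5,
  "r11_Vmax": 16,
  "r11_Km": 1,
  "r12_k": 0.3,
  "r13_kcat": 1,
  "r13_Km": 5,
  "r14_Vmax": 8,
  "r14_Km": 1,
  "r15_k": 0.3,
  "r16_k": 0.3,
  "r17_kcat": 3,
  "r17_Km": 50,
  "r18_Vmax": 12,
  "r18_Km": 5,
  "r19_kcat": 3,
  "r19_Km": 50,
  "r20_Vmax": 12,
  "r20_Km": 5,
  "r21_kon": 0.06,
  "r21_koff": 0.05,
  "r22_k": 0.3,
  "r23_Vmax": 8,
  "r23_Km": 200,
  "r24_kon": 0.000125,
  "r24_koff": 0.05,
  "r25_k": 0.05,
  "r26_Vmax": 2,
  "r26_Km": 200,
  "r27_kon": 0.05,
  "r27_koff": 0.01,
  "r28_Vmax": 1,
  "r28_Km": 100,
  "r29_kon": 0.05,
  "r29_koff": 0.5,
  "r30_k": 40,
  "r31_k": 0.03,
  "r32_k": 2,
  "r33_k": 0.3,
  "r34_k": 4,
  "r35_k": 3,
  "r36_kon": 1,
  "r36_koff": 0.05,
  "r37_k": 6,
  "r38_k": 0.15,
  "r39_k": 2,
  "r40_k": 0.2,
  "r41_k": 2,
  "r42_k": 3,
  "r43_kon": 0.05,
  "r43_koff": 0.5,
  "r44_k": 20,
  "r45_kon": 0.05,
  "r45_koff": 0.5,
  "r46_k": 20,
  "r47_k": 0.5,
  "r48_k": 0.05,
  "ic_Elk1": 56.312,
  "ic_ATF2": 56.312,
  "ERK_max": 100,
  "FRK_max": 100,
  "JNK_max": 100
}
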