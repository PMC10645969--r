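# Tentative biomolecular assignments for discriminatory wavenumber regions.
# Regions are non-overlapping; edit or extend as needed and pass the file
# to band_assignments(path = ...).
- {low: 3250, high: 3450, label: "Amide A / OH", modes: "O-H, C-H, N-H stretching"}
- {low: 2920, high: 2980, label: "lipid CH3/CH2", modes: "C-H stretching (lipid, protein)"}
- {low: 2850, high: 2895, label: "carbohydrate C-OH", modes: "C-OH deformation, C-O/C-C stretch"}
- {low: 2720, high: 2790, label: "lipid CH", modes: "C-H, CH2 stretching"}
- {low: 1600, high: 1700, label: "Amide I", modes: "C=O stretch, C-N stretch, N-H bend"}
- {low: 1500, high: 1565, label: "Amide II", modes: "N-H bending, C-N stretching"}
- {low: 1330, high: 1380, label: "protein/lipid CH", modes: "CH2/CH3 deformation"}
- {low: 1220, high: 1290, label: "Amide III / asym PO2-", modes: "N-H bend, C-N stretch, asym PO2- stretch"}
- {low: 1140, high: 1180, label: "asym PO2-", modes: "asymmetric PO2- stretching"}
- {low: 1050, high: 1095, label: "sym PO2-", modes: "symmetric PO2- stretching, C-O stretch"}
- {low: 1000, high: 1045, label: "carbohydrate", modes: "C-O and C-C stretching, C-OH deformation"}
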