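{"C1_P01_pt001_s1":{"site_id":"C1","patient_id":"C1_P01","point_id":"pt001","analyst_id":"A1","cautery_mode":"cut","tissue_label":"unassigned","tumor_cell_pct":0,"adipose_pure":true,"pik3ca_status":"unknown","hr_status":"ERPR_pos","lockmass_shift":null},"C1_P01_pt002_s1":{"site_id":"C1","patient_id":"C1_P01","point_id":"pt002","analyst_id":"A1","cautery_mode":"cut","tissue_label":"unassigned","tumor_cell_pct":60.0687651988119,"adipose_pure":false,"pik3ca_status":"Mut","hr_status":"ERPR_pos","lockmass_shift":null},"C1_P02_pt003_s1":{"site_id":"C1","patient_id":"C1_P02","point_id":"pt003","analyst_id":"A1","cautery_mode":"cut","tissue_label":"unassigned","tumor_cell_pct":65.2997096744366,"adipose_pure":false,"pik3ca_status":"Mut","hr_status":"triple_neg","lockmass_shift":null},"C1_P02_pt004_s1":{"site_id":"C1","patient_id":"C1_P02","point_id":"pt004","analyst_id":"A1","cautery_mode":"coag","tissue_label":"unassigned","tumor_cell_pct":0,"adipose_pure":true,"pik3ca_status":"unknown","hr_status":"triple_neg","lockmass_shift":null},"C3_P01_pt005_s1":{"site_id":"C3","patient_id":"C3_P01","point_id":"pt005","analyst_id":"A2","cautery_mode":"cut","tissue_label":"unassigned","tumor_cell_pct":47.4160798918456,"adipose_pure":false,"pik3ca_status":"WT","hr_status":"ERPR_pos","lockmass_shift":null},"C3_P01_pt006_s1":{"site_id":"C3","patient_id":"C3_P01","point_id":"pt006","analyst_id":"A2","cautery_mode":"coag","tissue_label":"unassigned","tumor_cell_pct":0,"adipose_pure":true,"pik3ca_status":"unknown","hr_status":"ERPR_pos","lockmass_shift":null},"C3_P02_pt007_s1":{"site_id":"C3","patient_id":"C3_P02","point_id":"pt007","analyst_id":"A2","cautery_mode":"coag","tissue_label":"unassigned","tumor_cell_pct":88.7695938092656,"adipose_pure":false,"pik3ca_status":"Mut","hr_status":"ERPR_pos","lockmass_shift":null},"C3_P02_pt008_s1":{"site_id":"C3","patient_id":"C3_P02","point_id":"pt008","analyst_id":"A2","cautery_mode":"coag","tissue_label":"unassigned","tumor_cell_pct":51.1196611193009,"adipose_pure":false,"pik3ca_status":"Mut","hr_status":"ERPR_pos","lockmass_shift":null},"C4_P01_pt009_s1":{"site_id":"C4","patient_id":"C4_P01","point_id":"pt009","analyst_id":"A3","cautery_mode":"cut","tissue_label":"unassigned","tumor_cell_pct":49.773355757352,"adipose_pure":false,"pik3ca_status":"Mut","hr_status":"ERPR_pos","lockmass_shift":null},"C4_P01_pt010_s1":{"site_id":"C4","patient_id":"C4_P01","point_id":"pt010","analyst_id":"A3","cautery_mode":"coag","tissue_label":"unassigned","tumor_cell_pct":40.5305851227604,"adipose_pure":false,"pik3ca_status":"Mut","hr_status":"ERPR_pos","lockmass_shift":null},"C4_P02_pt011_s1":{"site_id":"C4","patient_id":"C4_P02","point_id":"pt011","analyst_id":"A3","cautery_mode":"cut","tissue_label":"unassigned","tumor_cell_pct":0,"adipose_pure":true,"pik3ca_status":"unknown","hr_status":"ERPR_pos","lockmass_shift":null},"C4_P02_pt012_s1":{"site_id":"C4","patient_id":"C4_P02","point_id":"pt012","analyst_id":"A3","cautery_mode":"cut","tissue_label":"unassigned","tumor_cell_pct":57.5092632882297,"adipose_pure":false,"pik3ca_status":"WT","hr_status":"ERPR_pos","lockmass_shift":null}}
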