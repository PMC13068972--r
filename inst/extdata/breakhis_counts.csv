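class_label,subtype,X40,X100,X200,X400
benign,adenosis,114,113,111,106
benign,fibroadenoma,253,260,264,237
benign,phyllodes_tumor,109,121,108,115
benign,tubular_adenoma,149,150,140,130
malignant,ductal_carcinoma,864,903,896,788
malignant,lobular_carcinoma,156,170,163,137
malignant,mucinous_carcinoma,205,222,196,169
malignant,papillary_carcinoma,145,142,135,138
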