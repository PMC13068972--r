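model,magnification,class,precision,recall
baseline,40,benign,0.896,0.882
baseline,40,malignant,0.888,0.901
baseline,100,benign,0.912,0.898
baseline,100,malignant,0.904,0.917
baseline,200,benign,0.920,0.906
baseline,200,malignant,0.911,0.925
baseline,400,benign,0.927,0.913
baseline,400,malignant,0.918,0.932
gwo,40,benign,0.903,0.901
gwo,40,malignant,0.929,0.927
gwo,100,benign,0.910,0.908
gwo,100,malignant,0.939,0.937
gwo,200,benign,0.919,0.917
gwo,200,malignant,0.938,0.936
gwo,400,benign,0.924,0.922
gwo,400,malignant,0.948,0.946
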