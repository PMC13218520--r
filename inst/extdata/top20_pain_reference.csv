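description,share_pct,category,unit_price,overall_price
PARA CPLT 16,5.08,Pain Relief Oral,0.04,4.17
VALUE HEALTH PARA CAPLETS 16 16,4.57,Pain Relief Oral,0.02,1.72
PARA CPLT 32,4.32,Pain Relief Oral,0.06,1.32
PA&CO CPL32,4.03,Pain Relief Oral,0.13,1.40
PARA&COD EFF 32,3.63,Pain Relief Oral,0.05,4.39
VALUE HEALTH IBUPROFEN TABS 16,3.60,Pain Relief Oral,0.03,1.60
PARA EXT TAB16,3.43,Pain Relief Oral,0.11,0.63
IBU200MG CPL16,3.30,Pain Relief Oral,0.08,1.09
PARA TABS 16,2.53,Pain Relief Oral,0.03,5.41
PLUS SOL TAB 32,2.41,Pain Relief Oral,0.72,1.65
NUROFEN TABS 16,1.82,Pain Relief Oral,0.07,4.31
NUROFEN PLUS 32,1.70,Pain Relief Oral,0.90,0.38
PARA CAPS 16,1.63,Pain Relief Oral,0.09,1.06
PARA TB 32,1.53,Pain Relief Oral,0.11,1.13
ANADIN EXTRA CPL 16,1.48,Pain Relief Oral,0.13,0.40
SYNDOL CPL30,1.40,Pain Relief Oral,0.36,2.46
PARA & CODEINE TABS 32,1.39,Pain Relief Oral,0.12,1.54
Ibuprofen 200MG Caplets 16,1.35,Pain Relief Oral,0.13,0.66
NUROFEN CAPL 16,1.20,Pain Relief Oral,0.07,0.20
IBUPROFEN 400MG CPLT 48,1.05,Pain Relief Oral,0.35,0.43
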