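id,state,urbanicity,in_union,ethnic_group,age_group,education,is_mother,not_attending_school,working,poor_walls,house_or_apartment,electricity,internet,partner_same_ethnic,y_use_any,y_use_modern,y_unmet,weight
w0000015,1,rural,1,nonethnic,40-44,primary,0,1,0,1,0,0,0,1,0,0,0,2.1666666666666665
w0000009,1,rural,1,afro,35-39,primary,1,1,1,1,1,0,0,0,1,1,0,2.1666666666666665
w0000003,1,rural,1,indigenous,30-34,primary,1,1,0,0,1,0,0,0,0,0,0,2.1666666666666665
w0000001,1,rural,1,indigenous,40-44,secondary,1,1,0,0,1,1,0,1,1,1,0,2.1666666666666665
w0000010,1,rural,1,afro,40-44,secondary,1,0,0,1,0,1,0,1,0,0,0,2.1666666666666665
w0000004,1,rural,1,indigenous,25-29,none,1,1,0,0,1,1,0,1,0,0,1,2.1666666666666665
w0000029,1,urban,1,nonethnic,45-49,secondary,1,1,0,0,0,1,0,1,0,0,0,2
w0000025,1,urban,1,nonethnic,35-39,secondary,1,1,0,0,1,1,0,1,0,0,0,2
w0000012,1,urban,1,afro,45-49,secondary,1,1,1,0,1,1,1,1,1,1,0,2
w0000022,1,urban,1,nonethnic,20-24,higher,1,1,1,0,1,1,1,1,1,1,0,2
w0000021,1,urban,1,nonethnic,45-49,higher,1,1,0,0,1,1,1,1,0,0,1,2
w0000027,1,urban,1,nonethnic,30-34,higher,1,1,0,0,1,1,0,1,1,1,0,2
w0000007,1,urban,1,indigenous,35-39,secondary,1,1,1,0,1,1,0,1,1,1,0,2
w0000011,1,urban,1,afro,30-34,secondary,1,1,0,0,1,1,1,1,0,0,0,2
w0000047,2,rural,1,nonethnic,25-29,primary,1,1,1,0,1,0,0,1,1,0,0,2.1666666666666665
w0000039,2,rural,1,afro,45-49,primary,1,1,1,0,1,1,0,1,0,0,0,2.1666666666666665
w0000046,2,rural,1,nonethnic,40-44,higher,1,1,1,0,1,1,0,1,1,1,0,2.1666666666666665
w0000031,2,rural,1,indigenous,45-49,secondary,1,1,0,1,1,1,1,1,1,1,0,2.1666666666666665
w0000049,2,rural,1,nonethnic,35-39,primary,1,1,1,0,1,1,0,1,1,1,0,2.1666666666666665
w0000048,2,rural,1,nonethnic,45-49,secondary,1,1,1,0,1,1,0,1,1,1,0,2.1666666666666665
w0000051,2,urban,1,nonethnic,20-24,secondary,1,1,1,0,1,1,1,1,1,1,0,2
w0000052,2,urban,1,nonethnic,20-24,higher,1,1,1,0,1,1,1,1,0,0,1,2
w0000055,2,urban,1,nonethnic,25-29,secondary,1,1,1,0,1,1,1,0,1,1,0,2
w0000035,2,urban,1,indigenous,40-44,secondary,1,1,1,0,1,1,0,1,0,0,0,2
w0000050,2,urban,1,nonethnic,35-39,primary,0,1,1,0,1,1,0,1,1,1,0,2
w0000058,2,urban,1,nonethnic,25-29,higher,1,1,0,0,1,1,1,1,1,1,0,2
w0000042,2,urban,1,afro,25-29,secondary,1,1,1,0,1,1,1,1,1,1,0,2
w0000034,2,urban,1,indigenous,35-39,higher,1,1,1,0,1,1,0,1,1,1,0,2
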