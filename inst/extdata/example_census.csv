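id,in_union,state,ethnic_group,urbanicity,age_group,education,is_mother,not_attending_school,working,poor_walls,house_or_apartment,electricity,internet,partner_same_ethnic
w0000001,1,1,indigenous,rural,40-44,secondary,1,1,0,0,1,1,0,1
w0000002,1,1,indigenous,rural,20-24,primary,1,1,0,0,1,1,0,1
w0000003,1,1,indigenous,rural,30-34,primary,1,1,0,0,1,0,0,0
w0000004,1,1,indigenous,rural,25-29,none,1,1,0,0,1,1,0,1
w0000005,1,1,indigenous,urban,35-39,primary,0,1,0,0,0,1,1,1
w0000006,1,1,indigenous,urban,45-49,secondary,1,0,0,0,1,1,1,1
w0000007,1,1,indigenous,urban,35-39,secondary,1,1,1,0,1,1,0,1
w0000008,1,1,afro,rural,45-49,none,1,1,1,1,1,0,0,1
w0000009,1,1,afro,rural,35-39,primary,1,1,1,1,1,0,0,0
w0000010,1,1,afro,rural,40-44,secondary,1,0,0,1,0,1,0,1
w0000011,1,1,afro,urban,30-34,secondary,1,1,0,0,1,1,1,1
w0000012,1,1,afro,urban,45-49,secondary,1,1,1,0,1,1,1,1
w0000013,1,1,afro,urban,35-39,primary,1,1,1,0,1,1,0,1
w0000014,1,1,afro,urban,30-34,primary,0,1,0,0,1,1,1,1
w0000015,1,1,nonethnic,rural,40-44,primary,0,1,0,1,0,0,0,1
w0000016,1,1,nonethnic,rural,25-29,secondary,1,1,0,0,0,1,0,1
w0000017,1,1,nonethnic,rural,35-39,secondary,1,1,0,0,0,1,0,1
w0000018,1,1,nonethnic,rural,20-24,primary,1,1,0,1,1,1,0,1
w0000019,1,1,nonethnic,rural,45-49,primary,1,0,0,0,1,1,0,1
w0000020,1,1,nonethnic,rural,30-34,primary,1,1,0,0,1,1,1,1
w0000021,1,1,nonethnic,urban,45-49,higher,1,1,0,0,1,1,1,1
w0000022,1,1,nonethnic,urban,20-24,higher,1,1,1,0,1,1,1,1
w0000023,1,1,nonethnic,urban,25-29,secondary,1,1,1,0,1,1,0,1
w0000024,1,1,nonethnic,urban,15-19,secondary,1,1,0,0,1,1,1,1
w0000025,1,1,nonethnic,urban,35-39,secondary,1,1,0,0,1,1,0,1
w0000026,1,1,nonethnic,urban,40-44,primary,1,1,1,0,1,1,0,1
w0000027,1,1,nonethnic,urban,30-34,higher,1,1,0,0,1,1,0,1
w0000028,1,1,nonethnic,urban,15-19,secondary,0,1,0,0,1,1,1,1
w0000029,1,1,nonethnic,urban,45-49,secondary,1,1,0,0,0,1,0,1
w0000030,1,2,indigenous,rural,30-34,secondary,1,1,1,1,1,1,0,0
w0000031,1,2,indigenous,rural,45-49,secondary,1,1,0,1,1,1,1,1
w0000032,1,2,indigenous,rural,20-24,secondary,1,1,1,0,1,0,0,1
w0000033,1,2,indigenous,rural,45-49,primary,1,1,1,1,1,1,0,0
w0000034,1,2,indigenous,urban,35-39,higher,1,1,1,0,1,1,0,1
w0000035,1,2,indigenous,urban,40-44,secondary,1,1,1,0,1,1,0,1
w0000036,1,2,indigenous,urban,40-44,higher,1,1,0,0,1,1,0,0
w0000037,1,2,afro,rural,25-29,primary,0,0,1,0,1,0,1,1
w0000038,1,2,afro,rural,25-29,secondary,0,1,0,1,1,1,0,1
w0000039,1,2,afro,rural,45-49,primary,1,1,1,0,1,1,0,1
w0000040,1,2,afro,urban,15-19,secondary,1,1,1,1,1,1,0,1
w0000041,1,2,afro,urban,40-44,primary,1,1,1,0,1,1,1,1
w0000042,1,2,afro,urban,25-29,secondary,1,1,1,0,1,1,1,1
w0000043,1,2,afro,urban,30-34,higher,1,1,0,0,1,1,1,0
w0000044,1,2,nonethnic,rural,40-44,none,1,1,0,0,1,1,1,1
w0000045,1,2,nonethnic,rural,25-29,primary,1,1,0,1,1,1,0,1
w0000046,1,2,nonethnic,rural,40-44,higher,1,1,1,0,1,1,0,1
w0000047,1,2,nonethnic,rural,25-29,primary,1,1,1,0,1,0,0,1
w0000048,1,2,nonethnic,rural,45-49,secondary,1,1,1,0,1,1,0,1
w0000049,1,2,nonethnic,rural,35-39,primary,1,1,1,0,1,1,0,1
w0000050,1,2,nonethnic,urban,35-39,primary,0,1,1,0,1,1,0,1
w0000051,1,2,nonethnic,urban,20-24,secondary,1,1,1,0,1,1,1,1
w0000052,1,2,nonethnic,urban,20-24,higher,1,1,1,0,1,1,1,1
w0000053,1,2,nonethnic,urban,40-44,higher,1,1,1,0,1,1,1,1
w0000054,1,2,nonethnic,urban,30-34,secondary,1,0,1,0,1,1,1,1
w0000055,1,2,nonethnic,urban,25-29,secondary,1,1,1,0,1,1,1,0
w0000056,1,2,nonethnic,urban,45-49,secondary,0,1,1,0,1,1,0,1
w0000057,1,2,nonethnic,urban,45-49,secondary,1,1,1,0,1,1,1,1
w0000058,1,2,nonethnic,urban,25-29,higher,1,1,0,0,1,1,1,1
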