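chemical_id,smiles,class
lib001,CO,alkanol
lib002,CCO,alkanol
lib003,CCCO,alkanol
lib004,CCCCO,alkanol
lib005,CCCCCO,alkanol
lib006,CCCCCCO,alkanol
lib007,CC(C)O,alkanol
lib008,CC(C)CO,alkanol
lib009,CCC(C)O,alkanol
lib010,CCCCCCCO,alkanol
lib011,CC(C)CCO,alkanol
lib012,CCCCCCCCO,alkanol
lib013,CCC(C)CO,alkanol
lib014,CC(C)(C)O,alkanol
lib015,CCCC(C)O,alkanol
lib016,CCCCCCCCCO,alkanol
lib017,CC(=O)O,carboxylic_acid
lib018,CCC(=O)O,carboxylic_acid
lib019,CCCC(=O)O,carboxylic_acid
lib020,CCCCC(=O)O,carboxylic_acid
lib021,CCCCCC(=O)O,carboxylic_acid
lib022,CCCCCCC(=O)O,carboxylic_acid
lib023,CC(C)C(=O)O,carboxylic_acid
lib024,CC(C)CC(=O)O,carboxylic_acid
lib025,CCC(C)C(=O)O,carboxylic_acid
lib026,CCCCCCCC(=O)O,carboxylic_acid
lib027,CC(C)CCC(=O)O,carboxylic_acid
lib028,CCCCCCCCC(=O)O,carboxylic_acid
lib029,CCC(C)CC(=O)O,carboxylic_acid
lib030,CC(C)(C)C(=O)O,carboxylic_acid
lib031,CCCC(C)C(=O)O,carboxylic_acid
lib032,CCCCCCCCCC(=O)O,carboxylic_acid
lib033,c1ccccc1,benzene
lib034,Cc1ccccc1,benzene
lib035,CCc1ccccc1,benzene
lib036,c1ccccc1O,benzene
lib037,c1ccccc1N,benzene
lib038,Cc1ccccc1C,benzene
lib039,Cc1ccc(C)cc1,benzene
lib040,c1ccccc1C(=O)O,benzene
lib041,Cc1ccccc1O,benzene
lib042,c1ccccc1CO,benzene
lib043,CCc1ccccc1O,benzene
lib044,c1ccccc1CC(=O)O,benzene
lib045,Cc1ccc(O)cc1,benzene
lib046,c1ccccc1CN,benzene
lib047,CCc1ccc(C)cc1,benzene
lib048,c1ccccc1CCO,benzene
lib049,c1ccncc1,pyridine
lib050,Cc1ccncc1,pyridine
lib051,CCc1ccncc1,pyridine
lib052,Cc1cccnc1,pyridine
lib053,Cc1ccccn1,pyridine
lib054,c1ccncc1O,pyridine
lib055,Nc1ccncc1,pyridine
lib056,Cc1ccncc1C,pyridine
lib057,CCc1cccnc1,pyridine
lib058,c1ccncc1CO,pyridine
lib059,Cc1cc(C)ncc1,pyridine
lib060,c1ccncc1C(=O)O,pyridine
lib061,CCCc1ccncc1,pyridine
lib062,Cc1ncccc1O,pyridine
lib063,CCCCc1ccncc1,pyridine
lib064,Cc1ccnc(C)c1,pyridine
lib065,CN,primary_amine
lib066,CCN,primary_amine
lib067,CCCN,primary_amine
lib068,CCCCN,primary_amine
lib069,CCCCCN,primary_amine
lib070,CCCCCCN,primary_amine
lib071,CC(C)N,primary_amine
lib072,CC(C)CN,primary_amine
lib073,CCC(C)N,primary_amine
lib074,CCCCCCCN,primary_amine
lib075,CC(C)CCN,primary_amine
lib076,CCCCCCCCN,primary_amine
lib077,CCC(C)CN,primary_amine
lib078,CC(C)(C)N,primary_amine
lib079,CCCC(C)N,primary_amine
lib080,CCCCCCCCCN,primary_amine
lib081,COC(=O)C,ester
lib082,COC(=O)CC,ester
lib083,COC(=O)CCC,ester
lib084,COC(=O)CCCC,ester
lib085,COC(=O)CCCCC,ester
lib086,COC(=O)CCCCCC,ester
lib087,COC(=O)CC(C),ester
lib088,COC(=O)CC(C)C,ester
lib089,CCOC(=O)C,ester
lib090,CCOC(=O)CC,ester
lib091,CCOC(=O)CCC,ester
lib092,CCOC(=O)CCCC,ester
lib093,CCOC(=O)CCCCC,ester
lib094,CCOC(=O)CCCCCC,ester
lib095,CCOC(=O)CC(C),ester
lib096,CCOC(=O)CC(C)C,ester
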