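{"stip_output_hidden":[[11.9326298021389,23.8723229033736,29.8344825697855,0],[9.93403555787002,19.9004470119154,24.8640124340583,0]],"stip_desired_hidden":[[5.97295497717412,11.9445017765591,14.9288946792469,0],[3.9844428257317,7.96794509665965,9.95877418892507,0]],"stip_output_input":[[11.9326298021389,5.97047013572711,17.9018527676465],[9.93403555787002,4.97047013572711,14.9299768761883]],"stip_desired_input":[[5.97295497717412,2.98856207448637,8.95593970207276],[3.9844428257317,1.99361373346628,5.97433136319337]],"delta_w2":[[-0.595967482496481,-1.19278211268145,-1.49055878905386,-0],[-0.594959273213832,-1.19325019152558,-1.49052382451333,-0]],"delta_w1_bp":[[-0.595967482496481,-0.298190806124074,-0.894591306557377],[-0.595967482496481,-0.298190806124074,-0.894591306557377],[-0.594959273213832,-0.297685640226082,-0.895564551299496],[-0.594959273213832,-0.297685640226082,-0.895564551299496]],"delta_w1_fa":[[0.118487750001442,0.0592845450962207,0.179599532630959],[0.477177269710245,0.238754711258456,0.715283747349053],[-1.07122915456969,-0.535985702176346,-1.61172421891646],[-1.0729431103502,-0.536844484202931,-1.61006970285485]],"delta_w1_ba":[[-0.774556085388896,-0.387547014781698,-1.16316334747301],[-0.356673101143504,-0.178459834366252,-0.537630704202333],[-0.119798422068886,-0.0599412607636097,-0.178334314466204],[0.536874838888158,0.268624308460662,0.804645553530579]]}
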