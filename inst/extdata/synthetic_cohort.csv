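Pat,age,sex,t_dur,Sess,UPDRS,UPDRS_II,UPDRS_III,UPDRS_IV,HYsc,SEngs,PDQ39,AIMS,Epworth,SccDur,SccLat,SccAmp,SccVel
11,42,1,15,1,80,17,52,2,2,65,49,4,10,43,286,10,485.4
11,42,1,15,2,28,5,25,2,1.5,80,48,7,13,40,191.5,9,492.8
11,42,1,15,3,61,17,30,4,2.5,70,49,5,13,42,281,9,505.3
11,42,1,15,4,29,6,2,6,1.5,75,49,6,12,41,215.4,9,517.5
14,52,1,13,1,57,12,37,2,2,70,52,5,5,46,352.4,11,570.1
14,52,1,13,2,27,6,28,1,1,85,45,4,7,45,141,11,568
14,52,1,13,3,75,15,28,5,2,65,54,5,3,45,253.1,11,523.7
14,52,1,13,4,20,5,15,4,1,95,45,5,5,44,166.2,10,504.2
25,62,1,9,1,65,15,50,3,2.5,65,74,4,13,38,301,7,468.6
25,62,1,9,2,43,8,13,1,1.5,75,72,2,12,42,247.1,9,575.9
25,62,1,9,3,69,13,46,3,2,60,69,3,13,41,322.7,9,527.2
25,62,1,9,4,37,11,25,5,1.5,75,70,5,14,41,172.3,9,554.7
27,46,0,15,1,55,12,34,1,2,65,72,3,9,48,132.8,12,605
27,46,0,15,2,10,3,28,1,1,90,63,2,11,43,169.8,8,465.4
27,46,0,15,3,48,9,32,2,1.5,80,68,3,9,47,183.6,11,554.3
27,46,0,15,4,4,1,5,4,1,95,57,5,8,45,162.2,10,510.4
28,34,1,8,1,55,12,44,3,2,70,75,9,6,44,298.3,10,568.5
28,34,1,8,2,14,1,7,2,1.5,95,81,8,5,43,209,10,552.2
28,34,1,8,3,41,10,35,5,2,75,76,8,8,44,181.1,10,629.8
28,34,1,8,4,18,3,15,4,1.5,90,72,9,6,42,189.8,10,581.2
38,59,0,7,1,72,16,27,0,1.5,65,84,9,15,45,180,10,579.8
38,59,0,7,2,25,7,2,2,1,80,69,9,15,44,155.7,10,553.8
38,59,0,7,3,40,9,15,4,1.5,70,74,11,15,45,134.2,10,580.6
38,59,0,7,4,11,1,2,5,1,95,69,9,15,46,143,9,527.7
41,45,0,12,1,67,15,27,2,2,60,72,7,15,44,217,9,504.5
41,45,0,12,2,11,2,7,0,1,95,61,6,13,46,169.4,12,584.8
41,45,0,12,3,48,10,33,4,2,70,71,8,16,47,108.8,10,530.7
41,45,0,12,4,4,1,2,2,1,95,64,9,15,48,141.7,10,535.3
45,53,1,14,1,80,18,56,2,2.5,60,103,3,15,42,341,10,498.2
45,53,1,14,2,38,9,28,2,2,80,102,5,14,42,247.9,10,502.4
45,53,1,14,3,57,13,53,5,2.5,60,105,5,16,43,245.4,11,556
45,53,1,14,4,27,7,19,5,1.5,80,100,7,14,39,213.6,11,528.2
63,67,1,8,1,89,19,47,1,3,60,82,1,11,43,447.4,12,573.2
63,67,1,8,2,44,9,28,3,2,75,74,2,13,40,233.3,11,576.3
63,67,1,8,3,76,17,29,5,2.5,65,79,2,12,43,374.9,10,480.3
63,67,1,8,4,43,10,9,4,1.5,75,75,2,14,41,216.9,10,485.1
64,51,1,12,1,46,11,53,1,2.5,75,78,2,10,42,356.1,9,470.2
64,51,1,12,2,60,14,12,2,1.5,70,74,0,9,42,231.3,9,485
64,51,1,12,3,66,14,40,4,2,70,72,4,10,42,244.2,10,490.3
64,51,1,12,4,30,7,15,5,1.5,80,71,2,8,41,210.9,9,508.9
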