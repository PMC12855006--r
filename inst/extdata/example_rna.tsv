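sample_id	rna_f0001	rna_f0002	rna_f0003	rna_f0004	rna_f0005	rna_f0006	rna_f0007	rna_f0008	rna_f0009	rna_f0010	rna_f0011	rna_f0012
s0001	0.0721093331521453	-1.93407124181107	0.203848256100919	-0.742952770989744	0.0891515593668345	-1.82751219969303	-0.234821329520918	0.988430079942845	-0.329876590300003	1.21292288865414	0.242418462847319	2.48074047066389
s0002	-0.60304476352782	-1.12049773413154	1.13933913307141	-0.494057505399778	-0.656085894158696	-0.958336363378365	-3.03896487154097	0.665952563827918	0.164719295379507	0.596799329186056	-0.0941532151291122	1.53439069436005
s0003	-0.0764748608241257	-0.0699181650498124	0.0395260762776231	-0.0590755715067613	0.0471419261174591	-0.117798415868682	-0.0269526428068738	0.00543298162410936	0.158497051936103	-0.0858408185747309	0.0314676132232143	0.150145138985481
s0004	0.335148551192959	-1.4934539141998	-0.0869954956662805	-0.614755778131364	0.0817907875862891	-1.33546813577368	0.520840542097489	0.790654276560626	-0.425298333597644	1.07980599862589	0.1302433794639	2.01367533151282
s0005	0.108007335977954	-1.09014792380426	-0.0176972423577408	-0.340456343249897	0.0888039834557561	-1.00408004425593	0.185021439392775	0.438580826568565	-0.189624083067008	0.826275055742434	-0.123365769371786	1.28035366657067
s0006	-0.0905010834912551	-1.622647254327	0.782931899896826	-0.443114690929931	-0.161592577428105	-1.15068481228254	-1.62391915516183	1.17887323446526	0.0912162838346394	1.09777538086249	-0.0521253169428342	1.88751193530449
s0007	0.965517478256794	-2.64851665652373	-0.816791095023039	-0.987540493477655	0.617173435482799	-2.38315367292171	2.22062799661032	1.29437826019214	-1.03471440026584	1.99862613079544	0.418629655774884	3.48292965858198
s0008	0.251620119121469	-1.91107010039889	0.162514749634114	-0.63850037533153	-0.0622782411527824	-1.75596190585875	-0.177792806853807	1.09059768405518	-0.395652834290638	1.03508266413163	0.14723946370192	2.43553348466904
s0009	-0.366195647999506	-1.92319424445638	1.30379352686003	-0.931528178322996	-0.693904323500585	-1.62752386235009	-2.42731267556343	0.920320759123028	0.139348824072086	1.20837549247578	0.18096244336814	2.42518418463264
s0010	-1.16131933758272	-2.02118294342582	2.58168734659085	-0.663287923247773	-0.904237881022467	-1.44113791228344	-5.90948252432791	1.33556348118944	0.665059262945213	0.906569605973149	0.157544464275491	2.26349854378135
s0011	0.335157576620499	-0.199490493577982	-0.707037472945874	-0.0735353972453621	0.348640518202744	-0.333069705233133	1.48073284412591	-0.0799419842524977	-0.137267710063221	0.211082148857895	0.218621736623261	0.22295814823639
s0012	-0.260663787149247	-0.88865758233775	0.736401158744815	-0.447172073519722	-0.167210715792541	-0.89538402158482	-1.02862557667192	0.531181886462026	0.0290789495734035	0.432538367847246	0.0966072500001876	0.924865467613189
s0013	0.256089816812188	1.29546966488957	-0.512889560364787	0.594801166909593	0.191289748651403	1.05595501343022	0.781107771514603	-0.701790289015361	0.252855816560707	-0.90413021042837	-0.0506609942515641	-1.68590064886506
s0014	0.592279542854515	1.32137707504417	-1.45864525074403	0.545051852056373	0.658078579391867	1.16644167734179	3.16803533282979	-0.909124297934713	-0.170460919711129	-0.644893953109875	-0.0390612469017008	-1.71786467632929
s0015	0.461024123481586	2.24280006396043	-1.31465931248892	1.09048895523737	0.534013388093214	1.91682277649338	2.89910905220012	-1.2113727226464	-0.0571285905837663	-1.38527156833182	0.041501149335954	-2.94369544092946
s0016	0.331775567926674	2.12928912976959	-1.1067955115117	0.796880880899957	0.495020804271022	1.7759634900699	2.32133861870597	-1.29943494117008	0.0531192488278463	-1.42669178118761	-0.0579030599938113	-2.53947433135815
s0017	0.660682566807388	0.743331514463998	-1.42823304875866	0.337769757209725	0.558029154370589	0.78722032011867	3.14349804020162	-0.69398810176966	-0.508637222373212	-0.460314751924286	-0.0980376352742187	-1.05606820110148
s0018	0.590706352858698	1.01405596233259	-1.01707372085334	0.272691721672873	0.402082742165322	0.586847628264823	2.71106749757737	-0.701523281904369	-0.322388243072238	-0.281132955268962	-0.00312839523539641	-0.979589184956582
s0019	0.153049380181718	1.7017658819584	-0.720156425833613	0.747345749996255	0.328482892816489	1.69352243645056	1.2006462545236	-1.10182421605423	0.269905109450592	-1.19977891935285	-0.324245228549589	-2.49253522828755
s0020	-1.10872242045226	1.93054340369924	1.03120127379988	0.853485348755894	-0.51014333167451	1.79029930245337	-3.1729434994189	-0.779454750996085	1.10127580583451	-1.46067232294422	-0.319845901470787	-2.65186721179338
s0021	0.410448407624322	1.35735292737048	-1.16402131819748	0.527176879073019	0.435884491943565	1.27972689579915	2.57966339490625	-0.840349694371416	-0.204893011212373	-0.727629788317073	-0.31263140019561	-1.73108566728681
s0022	0.106841658277944	2.29154921211691	-0.60685435401119	1.05267059203293	0.0459709541612564	2.12494357180753	0.981174121108089	-1.1813364990864	0.265255353164019	-1.51667384285402	-0.0574493317636759	-3.06312707180069
s0023	-0.049857018319921	2.07752954986973	-0.254121045090524	0.644884644486636	0.194429966683817	1.61929610514951	0.685748637539105	-1.04999111695909	0.262773822163971	-1.23489899145672	-0.213575717326402	-2.62799319259635
s0024	-0.664321299172336	0.670867195128211	0.848334001938345	0.171340667718989	-0.43748333438469	0.544795558780482	-2.27410528571373	-0.207126222656247	0.687762946955571	-0.641355406192852	-0.181636649625594	-0.898326893453949
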