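mdp;

formula f11 = x1+u-x1*u;
formula f12 = x1*x2;
formula f21 = x1*(1-u);
formula f22 = x2;

module SWITCH
	s : bool init false;
	[PBN] true -> 0.3 : (s'=true) + 0.7 : (s'=false);
endmodule

module PER1
	p1 : [0..1] init 0;
	[PBN] true -> 0.1 : (p1'=1) + 0.9 : (p1'=0);
endmodule

module PER2
	p2 : [0..1] init 0;
	[PBN] true -> 0.1 : (p2'=1) + 0.9 : (p2'=0);
endmodule

module NODE1
	x1 : [0..1] init 1;
	d1 : [1..2] init 1;
	[PBN] p1=0 & s=true -> 0.3 : (x1'=f11) & (d1'=1) + 0.7 : (x1'=f12) & (d1'=2);
	[PBN] p1=0 & s=false & d1=1 -> (x1'=f11);
	[PBN] p1=0 & s=false & d1=2 -> (x1'=f12);
	[PBN] p1=1 & s=true -> 0.3 : (x1'=1-x1) & (d1'=1) + 0.7 : (x1'=1-x1) & (d1'=2);
	[PBN] p1=1 & s=false -> (x1'=1-x1);
endmodule

module NODE2
	x2 : [0..1] init 1;
	d2 : [1..2] init 1;
	[PBN] p2=0 & s=true -> 0.2 : (x2'=f21) & (d2'=1) + 0.8 : (x2'=f22) & (d2'=2);
	[PBN] p2=0 & s=false & d2=1 -> (x2'=f21);
	[PBN] p2=0 & s=false & d2=2 -> (x2'=f22);
	[PBN] p2=1 & s=true -> 0.2 : (x2'=1-x2) & (d2'=1) + 0.8 : (x2'=1-x2) & (d2'=2);
	[PBN] p2=1 & s=false -> (x2'=1-x2);
endmodule

module INPUT
	u : [0..1] init 0;
	[PBN] true -> (u'=0);
	[PBN] true -> (u'=1);
endmodule

module STEP
	t : [0..5] init 0;
	[PBN] t<5 -> (t'=t+1);
	[PBN] t=5 -> (t'=5);
endmodule

rewards "cost"
	[PBN] t<=3 & u=1 : 1;
	t=4 & x1=0 & x2=1 : 2;
	t=4 & x1=1 & x2=0 : 4;
	t=4 & x1=1 & x2=1 : 6;
endrewards

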