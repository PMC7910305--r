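site,bank_type,location,year,entry
N1,RB,Pathrahna,2015,+
N1,RB,Pathrahna,2016,+
N1,RB,Pathrahna,2017,3
N1,RB,Pathrahna,2018,5
N1,RB,Pathrahna,2019,13
N2,RB,Amba ghat,2015,+
N2,RB,Amba ghat,2016,+
N2,RB,Amba ghat,2017,2
N2,RB,Amba ghat,2018,3
N2,RB,Amba ghat,2019,-
N3,RB,Amba ghat,2015,0
N3,RB,Amba ghat,2016,0
N3,RB,Amba ghat,2017,2
N3,RB,Amba ghat,2018,1
N3,RB,Amba ghat,2019,-
N4,SB,Bhawanipur ghat,2015,+
N4,SB,Bhawanipur ghat,2016,+
N4,SB,Bhawanipur ghat,2017,21
N4,SB,Bhawanipur ghat,2018,15
N4,SB,Bhawanipur ghat,2019,6
N5,SB,Bhawanipur ghat,2015,+
N5,SB,Bhawanipur ghat,2016,+
N5,SB,Bhawanipur ghat,2017,1
N5,SB,Bhawanipur ghat,2018,-
N5,SB,Bhawanipur ghat,2019,-
N6,SB,Cement tower,2015,0
N6,SB,Cement tower,2016,0
N6,SB,Cement tower,2017,0
N6,SB,Cement tower,2018,1
N6,SB,Cement tower,2019,-
N7,SB,Cement tower,2015,+
N7,SB,Cement tower,2016,+
N7,SB,Cement tower,2017,1
N7,SB,Cement tower,2018,-
N7,SB,Cement tower,2019,-
N8,RB,Madho nala,2015,0
N8,RB,Madho nala,2016,+
N8,RB,Madho nala,2017,2
N8,RB,Madho nala,2018,-
N8,RB,Madho nala,2019,-
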