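"Serial No.","Clinical setting","Treatment intent","Date of most recent clinical progression of disease (cPD)","Anti-cancer modality","Start date","Stop date","Reason for stopping","Comments","Line of therapy N (CLoT + PLoT)","Agents","Primary ID","Preplanned with previous"
1,2A Early,3A Curative,NA (Date of diagnosis: 1999 Dec 20),"5A: i, ii; 5C; 5D",2000 Jan 01,2005 Aug 14,8B Completed,"5FU + epirubicin 75 + cyclophosphamide x6 -> breast conserving surgery -> EBRT -> tamoxifen x 2 yrs -> letrozole x 3 yrs",,"5-fluorouracil|fluoropyrimidine|i|;epirubicin|anthracycline|i|;cyclophosphamide|alkylating agent|i|;tamoxifen|selective estrogen receptor modulator|ii|;letrozole|aromatase inhibitor|ii|",P1,false
2,2A Early,3A Curative,2010 Dec 22,5A: ii; 5C,2011 Jan 01,2013 Jan 01,8B Completed,"Isolated local recurrence, mastectomy, letrozole x 2 yrs",,letrozole|aromatase inhibitor|ii|,P1,false
3,2B Locally advanced,3B Palliative,2015 Feb 01,5A: ii,2015 Feb 07,2016 Sep 19,8A cPD,Anastrozole,,anastrozole|aromatase inhibitor|ii|,P1,false
4,2C Metastatic,3B Palliative,2016 Sep 15,"5A: ii, iii",2016 Oct 02,2017 Jan 07,8A cPD,Everolimus + Exemestane,,everolimus|mTOR inhibitor|iii|;exemestane|aromatase inhibitor|ii|,P1,false
5,2C Metastatic,3B Palliative,2017 Jan 07,5A: i,2017 Feb 01,2017 Jul 17,8C Toxicity,Paclitaxel (stopped due to neuropathy),,paclitaxel|taxane|i|,P1,false
6,2C Metastatic,3B Palliative,2017 Jan 07,5A: i,2017 Aug 09,2017 Dec 23,8A cPD,Docetaxel,,docetaxel|taxane|i|,P1,false
7,2C Metastatic,3B Palliative,2017 Dec 17,5A: i,2018 Jan 08,2018 Aug 15,8A cPD,Capecitabine,,capecitabine|fluoropyrimidine|i|,P1,false
8,2C Metastatic,3B Palliative,2018 Aug 15,5A: i,2018 Sep 01,2018 Dec 30,8A cPD,Eribulin,,eribulin|halichondrin microtubule inhibitor|i|,P1,false
9,2C Metastatic,3B Palliative,2019 Jan 03,5A: ii,2019 Jan 27,2019 Jun 15,8A cPD,Fulvestrant,,fulvestrant|selective estrogen receptor degrader|ii|,P1,false
10,2C Metastatic,3B Palliative,2019 Jun 04,5B: iii,2019 Jun 22,2020 Apr 30,8A cPD,Experimental agent (small molecule),,experimental small molecule|experimental kinase inhibitor|iii|experimental,P1,false
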