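case_id,age,sex,icd_codes,ops_codes,ops_dates,admission_date,discharge_date,discharge_reason
A001,60,female,I50.1|E11.9,5-511.2,2017-03-02,2017-03-01,2017-03-10,01
A002,45,male,J44.9,5-530|5-511,2016-05-04|2016-05-01,2016-05-01,2016-06-01,07
A003,82,other,,5-530,,2015-01-01,2015-01-03,01
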