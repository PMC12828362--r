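study_id,timing,grade,category,count
Yamaguchi,acute,3,perforation_tof,2
Yamaguchi,acute,3,oesophagitis_dysphagia,1
Yamaguchi,acute,4,perforation_tof,1
Yamaguchi,late,3,stenosis,1
Yamaguchi,late,3,perforation_tof,1
Yamaguchi,late,5,bleeding,1
Kim,acute,5,perforation_tof,3
McAvoy,late,4,perforation_tof,1
Griffioen,late,3,oesophagitis_dysphagia,1
Kilburn,late,5,bleeding,1
Binkley,late,3,oesophagitis_dysphagia,1
Katano,late,3,oesophagitis_dysphagia,1
Hong_2018,late,3,perforation_tof,3
Zhou,late,5,perforation_tof,11
Chen,acute,3,oesophagitis_dysphagia,19
Chen,late,4,perforation_tof,7
Schlampp,late,3,stenosis,1
Schlampp,late,4,perforation_tof,1
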