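animal_id,group,death_age_d,censored,seizure_events
a1,CON,500,TRUE,"[{""age_d"":100,""racine_level"":3}]"
a2,CON,500,TRUE,"[]"
a3,DLX,150,FALSE,"[{""age_d"":60,""racine_level"":4},{""age_d"":80,""racine_level"":5}]"
a4,DLX,500,TRUE,"[{""age_d"":90,""racine_level"":5}]"
a5,DLX,500,TRUE,"[{""age_d"":30,""racine_level"":2},{""age_d"":120,""racine_level"":4}]"
a6,VIP,500,TRUE,"[{""age_d"":200,""racine_level"":3},{""age_d"":250,""racine_level"":3}]"
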