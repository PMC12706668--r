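"respondent_id","requirement_id","functional","dysfunctional"
"r001","A1",5,1
"r002","A1",5,1
"r003","A1",5,1
"r004","A1",5,1
"r005","A1",5,1
"r006","A1",5,1
"r007","A1",5,1
"r008","A1",5,1
"r009","A1",5,1
"r010","A1",5,1
"r011","A1",4,1
"r012","A1",4,1
"r013","A1",4,1
"r014","A1",4,1
"r015","A1",4,1
"r016","A1",4,1
"r017","A1",4,1
"r018","A1",4,1
"r019","A1",4,1
"r020","A1",4,1
"r021","A1",4,1
"r022","A1",4,1
"r023","A1",4,1
"r024","A1",4,1
"r025","A1",4,1
"r026","A1",4,1
"r027","A1",4,1
"r028","A1",4,1
"r029","A1",3,3
"r030","A1",3,3
"r031","A1",3,3
"r032","A1",3,3
"r001","A2",5,1
"r002","A2",5,1
"r003","A2",5,1
"r004","A2",5,1
"r005","A2",5,1
"r006","A2",5,1
"r007","A2",5,1
"r008","A2",5,1
"r009","A2",5,1
"r010","A2",5,1
"r011","A2",5,1
"r012","A2",5,1
"r013","A2",5,1
"r014","A2",5,1
"r015","A2",4,1
"r016","A2",4,1
"r017","A2",4,1
"r018","A2",4,1
"r019","A2",4,1
"r020","A2",4,1
"r021","A2",4,1
"r022","A2",4,1
"r023","A2",4,1
"r024","A2",4,1
"r025","A2",4,1
"r026","A2",4,1
"r027","A2",4,1
"r028","A2",4,1
"r029","A2",4,1
"r030","A2",3,3
"r031","A2",3,3
"r032","A2",3,3
"r001","A3",5,2
"r002","A3",5,2
"r003","A3",5,2
"r004","A3",5,2
"r005","A3",5,2
"r006","A3",5,2
"r007","A3",5,2
"r008","A3",5,2
"r009","A3",5,1
"r010","A3",5,1
"r011","A3",5,1
"r012","A3",5,1
"r013","A3",5,1
"r014","A3",5,1
"r015","A3",5,1
"r016","A3",5,1
"r017","A3",5,1
"r018","A3",5,1
"r019","A3",5,1
"r020","A3",5,1
"r021","A3",5,1
"r022","A3",5,1
"r023","A3",5,1
"r024","A3",5,1
"r025","A3",5,1
"r026","A3",5,1
"r027","A3",4,1
"r028","A3",4,1
"r029","A3",3,3
"r030","A3",3,3
"r031","A3",3,3
"r032","A3",3,3
"r001","A4",5,1
"r002","A4",4,1
"r003","A4",3,3
"r004","A4",3,3
"r005","A4",3,3
"r006","A4",3,3
"r007","A4",3,3
"r008","A4",3,3
"r009","A4",1,3
"r010","A4",1,3
"r011","A4",1,3
"r012","A4",1,3
"r013","A4",1,3
"r014","A4",1,3
"r015","A4",1,3
"r016","A4",1,3
"r017","A4",1,3
"r001","M1",5,2
"r002","M1",5,2
"r003","M1",5,2
"r004","M1",5,2
"r005","M1",5,2
"r006","M1",5,2
"r007","M1",5,2
"r008","M1",5,2
"r009","M1",5,2
"r010","M1",5,2
"r011","M1",5,2
"r012","M1",5,2
"r013","M1",5,2
"r014","M1",5,2
"r015","M1",5,1
"r016","M1",5,1
"r017","M1",5,1
"r018","M1",5,1
"r019","M1",5,1
"r020","M1",5,1
"r021","M1",5,1
"r022","M1",5,1
"r023","M1",5,1
"r024","M1",5,1
"r025","M1",5,1
"r026","M1",5,1
"r027","M1",5,1
"r028","M1",5,1
"r029","M1",5,1
"r030","M1",3,3
"r031","M1",3,3
"r032","M1",3,3
"r001","M2",5,2
"r002","M2",5,2
"r003","M2",5,2
"r004","M2",5,2
"r005","M2",5,2
"r006","M2",5,2
"r007","M2",5,2
"r008","M2",5,2
"r009","M2",5,2
"r010","M2",5,2
"r011","M2",5,2
"r012","M2",5,2
"r013","M2",5,2
"r014","M2",5,2
"r015","M2",5,2
"r016","M2",5,2
"r017","M2",5,2
"r018","M2",5,2
"r019","M2",5,2
"r020","M2",5,2
"r021","M2",5,1
"r022","M2",5,1
"r023","M2",5,1
"r024","M2",5,1
"r025","M2",5,1
"r026","M2",5,1
"r027","M2",5,1
"r028","M2",5,1
"r029","M2",5,1
"r030","M2",5,1
"r031","M2",5,1
"r032","M2",3,3
"r001","M3",5,2
"r002","M3",5,2
"r003","M3",5,2
"r004","M3",5,2
"r005","M3",5,2
"r006","M3",5,2
"r007","M3",5,2
"r008","M3",5,2
"r009","M3",5,2
"r010","M3",5,2
"r011","M3",5,2
"r012","M3",5,2
"r013","M3",5,2
"r014","M3",5,2
"r015","M3",5,1
"r016","M3",5,1
"r017","M3",5,1
"r018","M3",5,1
"r019","M3",5,1
"r020","M3",5,1
"r021","M3",5,1
"r022","M3",5,1
"r023","M3",5,1
"r024","M3",5,1
"r025","M3",5,1
"r026","M3",5,1
"r027","M3",5,1
"r028","M3",4,1
"r029","M3",4,1
"r030","M3",4,1
"r031","M3",4,1
"r032","M3",3,3
"r001","M4",5,2
"r002","M4",5,2
"r003","M4",5,2
"r004","M4",5,2
"r005","M4",5,2
"r006","M4",5,2
"r007","M4",5,2
"r008","M4",5,2
"r009","M4",5,2
"r010","M4",5,2
"r011","M4",5,2
"r012","M4",5,1
"r013","M4",5,1
"r014","M4",5,1
"r015","M4",5,1
"r016","M4",5,1
"r017","M4",5,1
"r018","M4",5,1
"r019","M4",5,1
"r020","M4",5,1
"r021","M4",5,1
"r022","M4",5,1
"r023","M4",5,1
"r024","M4",5,1
"r025","M4",5,1
"r026","M4",4,1
"r027","M4",4,1
"r028","M4",4,1
"r029","M4",4,1
"r030","M4",4,1
"r031","M4",3,3
"r032","M4",3,3
"r001","M5",4,1
"r002","M5",3,3
"r003","M5",3,3
"r004","M5",3,3
"r005","M5",3,3
"r006","M5",3,3
"r007","M5",3,3
"r008","M5",1,3
"r009","M5",1,3
"r010","M5",1,3
"r011","M5",1,3
"r012","M5",1,3
"r013","M5",1,3
"r014","M5",1,3
"r015","M5",1,3
"r016","M5",1,3
"r017","M5",1,3
"r001","O1",5,2
"r002","O1",5,2
"r003","O1",5,2
"r004","O1",5,1
"r005","O1",5,1
"r006","O1",5,1
"r007","O1",5,1
"r008","O1",5,1
"r009","O1",5,1
"r010","O1",5,1
"r011","O1",4,1
"r012","O1",4,1
"r013","O1",4,1
"r014","O1",4,1
"r015","O1",4,1
"r016","O1",4,1
"r017","O1",4,1
"r018","O1",4,1
"r019","O1",4,1
"r020","O1",4,1
"r021","O1",4,1
"r022","O1",4,1
"r023","O1",4,1
"r024","O1",4,1
"r025","O1",4,1
"r026","O1",4,1
"r027","O1",4,1
"r028","O1",4,1
"r029","O1",3,3
"r030","O1",3,3
"r031","O1",3,3
"r032","O1",3,3
"r001","O2",5,2
"r002","O2",5,2
"r003","O2",5,2
"r004","O2",5,2
"r005","O2",5,2
"r006","O2",5,1
"r007","O2",5,1
"r008","O2",5,1
"r009","O2",5,1
"r010","O2",5,1
"r011","O2",5,1
"r012","O2",5,1
"r013","O2",5,1
"r014","O2",5,1
"r015","O2",5,1
"r016","O2",5,1
"r017","O2",5,1
"r018","O2",5,1
"r019","O2",5,1
"r020","O2",5,1
"r021","O2",5,1
"r022","O2",4,1
"r023","O2",4,1
"r024","O2",4,1
"r025","O2",4,1
"r026","O2",4,1
"r027","O2",4,1
"r028","O2",4,1
"r029","O2",4,1
"r030","O2",4,1
"r031","O2",3,3
"r032","O2",3,3
"r001","O3",5,2
"r002","O3",5,2
"r003","O3",5,2
"r004","O3",5,2
"r005","O3",5,2
"r006","O3",5,1
"r007","O3",5,1
"r008","O3",5,1
"r009","O3",5,1
"r010","O3",5,1
"r011","O3",5,1
"r012","O3",5,1
"r013","O3",5,1
"r014","O3",5,1
"r015","O3",5,1
"r016","O3",5,1
"r017","O3",5,1
"r018","O3",4,1
"r019","O3",4,1
"r020","O3",4,1
"r021","O3",4,1
"r022","O3",4,1
"r023","O3",4,1
"r024","O3",4,1
"r025","O3",4,1
"r026","O3",4,1
"r027","O3",3,3
"r028","O3",3,3
"r029","O3",3,3
"r030","O3",3,3
"r031","O3",3,3
"r032","O3",3,3
"r001","O4",5,2
"r002","O4",5,2
"r003","O4",5,2
"r004","O4",5,2
"r005","O4",5,2
"r006","O4",5,2
"r007","O4",5,2
"r008","O4",5,2
"r009","O4",5,1
"r010","O4",5,1
"r011","O4",5,1
"r012","O4",5,1
"r013","O4",5,1
"r014","O4",5,1
"r015","O4",5,1
"r016","O4",5,1
"r017","O4",5,1
"r018","O4",5,1
"r019","O4",5,1
"r020","O4",5,1
"r021","O4",5,1
"r022","O4",5,1
"r023","O4",5,1
"r024","O4",5,1
"r025","O4",4,1
"r026","O4",4,1
"r027","O4",4,1
"r028","O4",4,1
"r029","O4",4,1
"r030","O4",3,3
"r031","O4",3,3
"r032","O4",3,3
"r001","O5",5,2
"r002","O5",5,2
"r003","O5",5,2
"r004","O5",5,2
"r005","O5",5,1
"r006","O5",5,1
"r007","O5",5,1
"r008","O5",5,1
"r009","O5",5,1
"r010","O5",5,1
"r011","O5",5,1
"r012","O5",5,1
"r013","O5",5,1
"r014","O5",5,1
"r015","O5",5,1
"r016","O5",5,1
"r017","O5",5,1
"r018","O5",5,1
"r019","O5",5,1
"r020","O5",5,1
"r021","O5",5,1
"r022","O5",4,1
"r023","O5",4,1
"r024","O5",4,1
"r025","O5",4,1
"r026","O5",4,1
"r027","O5",4,1
"r028","O5",4,1
"r029","O5",4,1
"r030","O5",3,3
"r031","O5",3,3
"r032","O5",3,3
"r001","O6",5,2
"r002","O6",5,2
"r003","O6",5,2
"r004","O6",5,1
"r005","O6",5,1
"r006","O6",5,1
"r007","O6",5,1
"r008","O6",5,1
"r009","O6",5,1
"r010","O6",5,1
"r011","O6",5,1
"r012","O6",4,1
"r013","O6",4,1
"r014","O6",4,1
"r015","O6",4,1
"r016","O6",4,1
"r017","O6",4,1
"r018","O6",4,1
"r019","O6",4,1
"r020","O6",4,1
"r021","O6",4,1
"r022","O6",4,1
"r023","O6",4,1
"r024","O6",4,1
"r025","O6",3,3
"r026","O6",3,3
"r027","O6",3,3
"r028","O6",3,3
"r029","O6",3,3
"r030","O6",3,3
"r031","O6",3,3
"r032","O6",3,3
"r001","O7",5,1
"r002","O7",4,1
"r003","O7",3,3
"r004","O7",1,3
"r005","O7",1,3
"r006","O7",1,3
"r007","O7",1,3
"r008","O7",1,3
"r009","O7",1,3
"r010","O7",1,3
"r011","O7",1,3
"r012","O7",1,3
"r013","O7",1,3
"r014","O7",1,3
"r015","O7",1,3
"r016","O7",1,3
"r017","O7",1,3
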