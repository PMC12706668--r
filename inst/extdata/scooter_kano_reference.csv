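"requirement_id","A","O","M","I","R","Q","classification","SI_printed","DSI_printed"
"A1",0,31.25,56.25,12.5,0,0,"M",87.5,-31.25
"A2",0,43.75,46.88,9.38,0,0,"M",90.63,-43.75
"A3",25,56.25,6.25,12.5,0,0,"O",62.5,-81.25
"A4",0,5.88,5.88,35.29,52.94,0,"R",25,-12.5
"M1",43.75,46.88,0,9.38,0,0,"O",46.88,-90.63
"M2",62.5,34.38,0,3.13,0,0,"A",34.3,-96.88
"M3",43.75,40.63,12.5,3.13,0,0,"A",53.1,-84.38
"M4",34.38,43.75,15.63,6.25,0,0,"O",59.3,-78.13
"M5",0,0,5.88,35.29,58.82,0,"R",14.29,0
"O1",9.38,21.88,56.25,12.5,0,0,"M",78.1,-31.25
"O2",15.63,50,28.13,6.25,0,0,"O",78.1,-65.63
"O3",15.63,37.5,28.13,18.75,0,0,"M",65.6,-53.13
"O4",25,50,15.63,9.38,0,0,"O",65.63,-75
"O5",12.5,53.13,25,9.38,0,0,"O",78.13,-65.63
"O6",9.38,25,40.63,25,0,0,"M",65.63,-34.38
"O7",0,5.88,5.88,5.88,82.35,0,"R",66.67,-33.33
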