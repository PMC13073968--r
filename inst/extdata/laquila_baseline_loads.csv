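node,role,served
AVEZZANO,hub,48319
Carsoli,spoke,15234
Civitella Roveto,spoke,17814
Trasacco,spoke,31706
L'AQUILA,hub,69717
Montereale,spoke,13101
Rocca di Mezzo,spoke,16797
San Demetrio ne' Vestini,spoke,12362
SULMONA,hub,40334
Castel di Sangro,spoke,14349
Castelvecchio Subequo,spoke,7099
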