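base	pos1	pos2	pos3	pos4	pos5	pos6	pos7	pos8	pos9	pos10	pos11	pos12
A	0.58369622027457524	0.62334649553432664	0	0.43024346608915259	0	2.0866148462239611	0	2.995659843501544	0	0	1.8204671074583576	0
C	0.6249136735934897	0.57139960870749862	0.45224107285199888	0.37699187436479459	0.41483577930556248	2.5487005247897758	2.9694747321887367	2.8666764970806553	2.3348180427455523	1.8628875793081909	1.8847757984340423	0.29754484655018659
G	0	0.47614267732822635	0.38385949840820394	0.39835536104231395	0.50630283597585135	2.9205864603850005	2.9322945172154107	2.4546134497199086	1.92672102841475	1.8339591109472666	2.2616125764435626	0.35206235011891812
T	0.50099539797324222	0	0.38592719377610196	0	0.59394667691901848	0	2.5722315907966373	0	1.8057086874617059	2.1483834503560613	0	0.3749995307142765
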