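cytotype,line,generation,mean_days
diploid,base,0,44.2
diploid,D1,1,39.1
diploid,D1,2,43.8
diploid,D1,3,42.5
diploid,D1,4,34.3
diploid,D2,1,37.2
diploid,D2,2,44.6
diploid,D2,3,41.6
diploid,D2,4,32.7
diploid,DC,1,40.5
diploid,DC,2,47.7
diploid,DC,3,45.3
diploid,DC,4,38.2
neotetraploid,base,0,47.1
neotetraploid,N1,1,41.0
neotetraploid,N1,2,48.3
neotetraploid,N1,3,44.4
neotetraploid,N1,4,35.3
neotetraploid,N2,1,43.2
neotetraploid,N2,2,48.4
neotetraploid,N2,3,43.2
neotetraploid,N2,4,37.3
neotetraploid,NC,1,41.2
neotetraploid,NC,2,51.0
neotetraploid,NC,3,48.1
neotetraploid,NC,4,42.1
tetraploid,base,0,50.3
tetraploid,T1,1,42.9
tetraploid,T1,2,50.3
tetraploid,T1,3,47.0
tetraploid,T1,4,38.4
tetraploid,T2,1,44.0
tetraploid,T2,2,52.1
tetraploid,T2,3,48.5
tetraploid,T2,4,40.2
tetraploid,TC,1,46.9
tetraploid,TC,2,55.7
tetraploid,TC,3,52.5
tetraploid,TC,4,44.2
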