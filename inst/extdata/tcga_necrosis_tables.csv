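table,variable,level,group,count,printed_percent
table1,er,positive,N-,292,89.6
table1,er,negative,N-,34,10.4
table1,er,positive,N+,73,48.7
table1,er,negative,N+,77,51.3
table1,pr,positive,N-,255,78.7
table1,pr,negative,N-,69,21.3
table1,pr,positive,N+,57,37.7
table1,pr,negative,N+,94,62.3
table1,her2,negative,N-,277,86.3
table1,her2,positive,N-,44,13.7
table1,her2,negative,N+,118,81.9
table1,her2,positive,N+,26,18.1
table1,pam50,LumA,N-,186,56.2
table1,pam50,LumB,N-,90,27.2
table1,pam50,Her2,N-,32,9.7
table1,pam50,Basal,N-,23,6.9
table1,pam50,LumA,N+,33,21.7
table1,pam50,LumB,N+,26,17.1
table1,pam50,Her2,N+,24,15.8
table1,pam50,Basal,N+,69,45.4
table3,er,positive,high,10,10.9
table3,er,negative,high,81,88.0
table3,er,positive,low,355,92.2
table3,er,negative,low,30,7.8
table3,pr,positive,high,5,5.6
table3,pr,negative,high,85,94.4
table3,pr,positive,low,307,79.7
table3,pr,negative,low,78,20.3
table3,her2,negative,high,87,95.6
table3,her2,positive,high,4,4.4
table3,her2,negative,low,308,82.4
table3,her2,positive,low,66,17.6
table3,pam50,LumA,high,0,0.0
table3,pam50,LumB,high,0,0.0
table3,pam50,Her2,high,2,2.2
table3,pam50,Basal,high,91,97.8
table3,pam50,LumA,low,219,56.2
table3,pam50,LumB,low,116,29.7
table3,pam50,Her2,low,54,13.8
table3,pam50,Basal,low,1,0.3
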