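# chromosome arm coordinates, GRCh37, 1-based closed
# boundaries are cytoband-derived centromere approximations (rounded)
chrom	arm	start	end
1	1p	1	125000000
1	1q	125000001	249250621
2	2p	1	93300000
2	2q	93300001	243199373
3	3p	1	91000000
3	3q	91000001	198022430
4	4p	1	50400000
4	4q	50400001	191154276
5	5p	1	48400000
5	5q	48400001	180915260
6	6p	1	61000000
6	6q	61000001	171115067
7	7p	1	59900000
7	7q	59900001	159138663
8	8p	1	45600000
8	8q	45600001	146364022
9	9p	1	49000000
9	9q	49000001	141213431
10	10p	1	40200000
10	10q	40200001	135534747
11	11p	1	53700000
11	11q	53700001	135006516
12	12p	1	35800000
12	12q	35800001	133851895
13	13p	1	17900000
13	13q	17900001	115169878
14	14p	1	17600000
14	14q	17600001	107349540
15	15p	1	19000000
15	15q	19000001	102531392
16	16p	1	36600000
16	16q	36600001	90354753
17	17p	1	24000000
17	17q	24000001	81195210
18	18p	1	17200000
18	18q	17200001	78077248
19	19p	1	26500000
19	19q	26500001	59128983
20	20p	1	27500000
20	20q	27500001	63025520
21	21p	1	13200000
21	21q	13200001	48129895
22	22p	1	14700000
22	22q	14700001	51304566
X	Xp	1	60600000
X	Xq	60600001	155270560
Y	Yp	1	12500000
Y	Yq	12500001	59373566
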