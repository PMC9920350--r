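L 12
J 3
0 0 1
1 0 1
2 0 2
3 0 2
6 0 1
7 0 1
8 0 2
9 0 2
0 1 1
1 1 1
4 1 2
5 1 2
6 1 1
7 1 1
10 1 2
11 1 2
2 2 1
3 2 1
4 2 2
5 2 2
8 2 1
9 2 1
10 2 2
11 2 2
0 3 2
1 3 2
2 3 1
3 3 1
6 3 2
7 3 2
8 3 1
9 3 1
0 4 2
1 4 2
4 4 1
5 4 1
6 4 2
7 4 2
10 4 1
11 4 1
2 5 2
3 5 2
4 5 1
5 5 1
8 5 2
9 5 2
10 5 1
11 5 1
0 6 1
1 6 1
2 6 2
3 6 2
6 6 1
7 6 1
8 6 2
9 6 2
0 7 1
1 7 1
4 7 2
5 7 2
6 7 1
7 7 1
10 7 2
11 7 2
2 8 1
3 8 1
4 8 2
5 8 2
8 8 1
9 8 1
10 8 2
11 8 2
0 9 2
1 9 2
2 9 1
3 9 1
6 9 2
7 9 2
8 9 1
9 9 1
0 10 2
1 10 2
4 10 1
5 10 1
6 10 2
7 10 2
10 10 1
11 10 1
2 11 2
3 11 2
4 11 1
5 11 1
8 11 2
9 11 2
10 11 1
11 11 1
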