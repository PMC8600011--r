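 A R N D C Q E G H I L K M F P S T W Y V
A 0.00 -6.30 -5.30 -5.30 0.70 -5.30 -5.30 -2.20 -5.00 2.70 2.00 -5.70 0.10 1.00 -3.40 -2.60 -2.50 -2.70 -3.10 2.40
R 6.30 0.00 1.00 1.00 7.00 1.00 1.00 4.10 1.30 9.00 8.30 0.60 6.40 7.30 2.90 3.70 3.80 3.60 3.20 8.70
N 5.30 -1.00 0.00 0.00 6.00 0.00 0.00 3.10 0.30 8.00 7.30 -0.40 5.40 6.30 1.90 2.70 2.80 2.60 2.20 7.70
D 5.30 -1.00 0.00 0.00 6.00 0.00 0.00 3.10 0.30 8.00 7.30 -0.40 5.40 6.30 1.90 2.70 2.80 2.60 2.20 7.70
C -0.70 -7.00 -6.00 -6.00 0.00 -6.00 -6.00 -2.90 -5.70 2.00 1.30 -6.40 -0.60 0.30 -4.10 -3.30 -3.20 -3.40 -3.80 1.70
Q 5.30 -1.00 0.00 0.00 6.00 0.00 0.00 3.10 0.30 8.00 7.30 -0.40 5.40 6.30 1.90 2.70 2.80 2.60 2.20 7.70
E 5.30 -1.00 0.00 0.00 6.00 0.00 0.00 3.10 0.30 8.00 7.30 -0.40 5.40 6.30 1.90 2.70 2.80 2.60 2.20 7.70
G 2.20 -4.10 -3.10 -3.10 2.90 -3.10 -3.10 0.00 -2.80 4.90 4.20 -3.50 2.30 3.20 -1.20 -0.40 -0.30 -0.50 -0.90 4.60
H 5.00 -1.30 -0.30 -0.30 5.70 -0.30 -0.30 2.80 0.00 7.70 7.00 -0.70 5.10 6.00 1.60 2.40 2.50 2.30 1.90 7.40
I -2.70 -9.00 -8.00 -8.00 -2.00 -8.00 -8.00 -4.90 -7.70 0.00 -0.70 -8.40 -2.60 -1.70 -6.10 -5.30 -5.20 -5.40 -5.80 -0.30
L -2.00 -8.30 -7.30 -7.30 -1.30 -7.30 -7.30 -4.20 -7.00 0.70 0.00 -7.70 -1.90 -1.00 -5.40 -4.60 -4.50 -4.70 -5.10 0.40
K 5.70 -0.60 0.40 0.40 6.40 0.40 0.40 3.50 0.70 8.40 7.70 0.00 5.80 6.70 2.30 3.10 3.20 3.00 2.60 8.10
M -0.10 -6.40 -5.40 -5.40 0.60 -5.40 -5.40 -2.30 -5.10 2.60 1.90 -5.80 0.00 0.90 -3.50 -2.70 -2.60 -2.80 -3.20 2.30
F -1.00 -7.30 -6.30 -6.30 -0.30 -6.30 -6.30 -3.20 -6.00 1.70 1.00 -6.70 -0.90 0.00 -4.40 -3.60 -3.50 -3.70 -4.10 1.40
P 3.40 -2.90 -1.90 -1.90 4.10 -1.90 -1.90 1.20 -1.60 6.10 5.40 -2.30 3.50 4.40 0.00 0.80 0.90 0.70 0.30 5.80
S 2.60 -3.70 -2.70 -2.70 3.30 -2.70 -2.70 0.40 -2.40 5.30 4.60 -3.10 2.70 3.60 -0.80 0.00 0.10 -0.10 -0.50 5.00
T 2.50 -3.80 -2.80 -2.80 3.20 -2.80 -2.80 0.30 -2.50 5.20 4.50 -3.20 2.60 3.50 -0.90 -0.10 0.00 -0.20 -0.60 4.90
W 2.70 -3.60 -2.60 -2.60 3.40 -2.60 -2.60 0.50 -2.30 5.40 4.70 -3.00 2.80 3.70 -0.70 0.10 0.20 0.00 -0.40 5.10
Y 3.10 -3.20 -2.20 -2.20 3.80 -2.20 -2.20 0.90 -1.90 5.80 5.10 -2.60 3.20 4.10 -0.30 0.50 0.60 0.40 0.00 5.50
V -2.40 -8.70 -7.70 -7.70 -1.70 -7.70 -7.70 -4.60 -7.40 0.30 -0.40 -8.10 -2.30 -1.40 -5.80 -5.00 -4.90 -5.10 -5.50 0.00
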