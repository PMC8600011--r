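 A R N D C Q E G H I L K M F P S T W Y V
A 0.00 84.80 25.50 22.50 19.90 55.20 49.80 -28.50 64.60 78.10 78.10 80.00 74.30 101.30 24.10 0.40 27.50 139.20 105.00 51.40
R -84.80 0.00 -59.30 -62.30 -64.90 -29.60 -35.00 -113.30 -20.20 -6.70 -6.70 -4.80 -10.50 16.50 -60.70 -84.40 -57.30 54.40 20.20 -33.40
N -25.50 59.30 0.00 -3.00 -5.60 29.70 24.30 -54.00 39.10 52.60 52.60 54.50 48.80 75.80 -1.40 -25.10 2.00 113.70 79.50 25.90
D -22.50 62.30 3.00 0.00 -2.60 32.70 27.30 -51.00 42.10 55.60 55.60 57.50 51.80 78.80 1.60 -22.10 5.00 116.70 82.50 28.90
C -19.90 64.90 5.60 2.60 0.00 35.30 29.90 -48.40 44.70 58.20 58.20 60.10 54.40 81.40 4.20 -19.50 7.60 119.30 85.10 31.50
Q -55.20 29.60 -29.70 -32.70 -35.30 0.00 -5.40 -83.70 9.40 22.90 22.90 24.80 19.10 46.10 -31.10 -54.80 -27.70 84.00 49.80 -3.80
E -49.80 35.00 -24.30 -27.30 -29.90 5.40 0.00 -78.30 14.80 28.30 28.30 30.20 24.50 51.50 -25.70 -49.40 -22.30 89.40 55.20 1.60
G 28.50 113.30 54.00 51.00 48.40 83.70 78.30 0.00 93.10 106.60 106.60 108.50 102.80 129.80 52.60 28.90 56.00 167.70 133.50 79.90
H -64.60 20.20 -39.10 -42.10 -44.70 -9.40 -14.80 -93.10 0.00 13.50 13.50 15.40 9.70 36.70 -40.50 -64.20 -37.10 74.60 40.40 -13.20
I -78.10 6.70 -52.60 -55.60 -58.20 -22.90 -28.30 -106.60 -13.50 0.00 0.00 1.90 -3.80 23.20 -54.00 -77.70 -50.60 61.10 26.90 -26.70
L -78.10 6.70 -52.60 -55.60 -58.20 -22.90 -28.30 -106.60 -13.50 0.00 0.00 1.90 -3.80 23.20 -54.00 -77.70 -50.60 61.10 26.90 -26.70
K -80.00 4.80 -54.50 -57.50 -60.10 -24.80 -30.20 -108.50 -15.40 -1.90 -1.90 0.00 -5.70 21.30 -55.90 -79.60 -52.50 59.20 25.00 -28.60
M -74.30 10.50 -48.80 -51.80 -54.40 -19.10 -24.50 -102.80 -9.70 3.80 3.80 5.70 0.00 27.00 -50.20 -73.90 -46.80 64.90 30.70 -22.90
F -101.30 -16.50 -75.80 -78.80 -81.40 -46.10 -51.50 -129.80 -36.70 -23.20 -23.20 -21.30 -27.00 0.00 -77.20 -100.90 -73.80 37.90 3.70 -49.90
P -24.10 60.70 1.40 -1.60 -4.20 31.10 25.70 -52.60 40.50 54.00 54.00 55.90 50.20 77.20 0.00 -23.70 3.40 115.10 80.90 27.30
S -0.40 84.40 25.10 22.10 19.50 54.80 49.40 -28.90 64.20 77.70 77.70 79.60 73.90 100.90 23.70 0.00 27.10 138.80 104.60 51.00
T -27.50 57.30 -2.00 -5.00 -7.60 27.70 22.30 -56.00 37.10 50.60 50.60 52.50 46.80 73.80 -3.40 -27.10 0.00 111.70 77.50 23.90
W -139.20 -54.40 -113.70 -116.70 -119.30 -84.00 -89.40 -167.70 -74.60 -61.10 -61.10 -59.20 -64.90 -37.90 -115.10 -138.80 -111.70 0.00 -34.20 -87.80
Y -105.00 -20.20 -79.50 -82.50 -85.10 -49.80 -55.20 -133.50 -40.40 -26.90 -26.90 -25.00 -30.70 -3.70 -80.90 -104.60 -77.50 34.20 0.00 -53.60
V -51.40 33.40 -25.90 -28.90 -31.50 3.80 -1.60 -79.90 13.20 26.70 26.70 28.60 22.90 49.90 -27.30 -51.00 -23.90 87.80 53.60 0.00
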