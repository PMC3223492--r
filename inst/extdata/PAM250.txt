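   A R N D C Q E G H I L K M F P S T W Y V
A 1.8272 -1.5519 0.1645 0.2877 -2.0365 -0.4490 0.3102 1.2687 -1.3704 -0.5175 -1.9050 -1.1653 -1.1396 -3.5487 1.1213 1.1118 1.2043 -5.7850 -3.5061 0.1942
R -1.5519 6.1321 -0.0062 -1.3007 -3.6933 1.2620 -1.0655 -2.5630 1.5606 -2.0258 -3.0411 3.3936 -0.4452 -4.4583 -0.1880 -0.3279 -0.8732 2.1698 -4.2232 -2.5279
N 0.1645 -0.0062 2.0364 2.0838 -3.6422 0.7774 1.4413 0.3559 1.5985 -1.8249 -2.9047 1.0014 -1.7461 -3.5205 -0.5012 0.6998 0.4429 -4.0257 -2.0789 -1.7729
D 0.2877 -1.3007 2.0838 3.8920 -5.1422 1.6493 3.4392 0.5925 0.6877 -2.3828 -4.0285 0.0744 -2.6280 -5.6553 -0.9586 0.2828 -0.1520 -6.7108 -4.3384 -2.1492
C -2.0365 -3.6933 -3.6422 -5.1422 11.9436 -5.4000 -5.3121 -3.3666 -3.4836 -2.3130 -6.0708 -5.4497 -5.2443 -4.3151 -2.7737 -0.0473 -2.2183 -7.7255 0.3319 -1.9399
Q -0.4490 1.2620 0.7774 1.6493 -5.4000 4.0893 2.4977 -1.2266 2.9451 -2.0563 -1.7891 0.7309 -0.9972 -4.6687 0.2281 -0.5182 -0.8044 -4.7519 -4.0511 -1.8880
E 0.3102 -1.0655 1.4413 3.4392 -5.3121 2.4977 3.8564 0.1755 0.6561 -2.0468 -3.3695 -0.0631 -2.1379 -5.4507 -0.5683 -0.0160 -0.4009 -6.9655 -4.2982 -1.8124
G 1.2687 -2.5630 0.3559 0.5925 -3.3666 -1.2266 0.1755 4.7851 -2.1427 -2.5603 -4.0703 -1.6905 -2.8135 -4.8453 -0.5104 1.0688 -0.0156 -6.9726 -5.2708 -1.3494
H -1.3704 1.5606 1.5985 0.6877 -3.4836 2.9451 0.6561 -2.1427 6.5634 -2.4704 -2.1081 -0.0612 -2.1719 -1.8102 -0.2399 -0.8203 -1.3232 -2.6524 -0.0901 -2.2665
I -0.5175 -2.0258 -1.8249 -2.3828 -2.3130 -2.0563 -2.0468 -2.5603 -2.4704 4.5572 2.4319 -1.9512 2.1799 1.0034 -2.0452 -1.4277 0.0726 -5.2156 -1.0004 3.7087
L -1.9050 -3.0411 -2.9047 -4.0285 -6.0708 -1.7891 -3.3695 -4.0703 -2.1081 2.4319 5.9721 -2.8759 3.6987 1.8057 -2.5551 -2.8295 -1.7096 -1.9282 -0.9305 1.8506
K -1.1653 3.3936 1.0014 0.0744 -5.4497 0.7309 -0.0631 -1.6905 -0.0612 -1.9512 -2.8759 4.6901 0.4154 -5.2872 -1.1569 -0.1720 -0.0192 -3.4677 -4.4693 -2.4672
M -1.1396 -0.4452 -1.7461 -2.6280 -5.2443 -0.9972 -2.1379 -2.8135 -2.1719 2.1799 3.6987 0.4154 6.4875 0.1664 -2.0846 -1.5693 -0.5935 -4.2838 -2.4955 1.7919
F -3.5487 -4.4583 -3.5205 -5.6553 -4.3151 -4.6687 -5.4507 -4.8453 -1.8102 1.0034 1.8057 -5.2872 0.1664 9.0796 -4.5792 -3.2330 -3.1559 0.2932 6.9751 -1.1811
P 1.1213 -0.1880 -0.5012 -0.9586 -2.7737 0.2281 -0.5683 -0.5104 -0.2399 -2.0452 -2.5551 -1.1569 -2.0846 -4.5792 5.8859 0.9510 0.3098 -5.5999 -4.9593 -1.2210
S 1.1118 -0.3279 0.6998 0.2828 -0.0473 -0.5182 -0.0160 1.0688 -0.8203 -1.4277 -2.8295 -0.1720 -1.5693 -3.2330 0.9510 1.6077 1.3554 -2.4631 -2.8541 -0.9864
T 1.2043 -0.8732 0.4429 -0.1520 -2.2183 -0.8044 -0.4009 -0.0156 -1.3232 0.0726 -1.7096 -0.0192 -0.5935 -3.1559 0.3098 1.3554 2.6005 -5.1404 -2.7775 0.2837
W -5.7850 2.1698 -4.0257 -6.7108 -7.7255 -4.7519 -6.9655 -6.9726 -2.6524 -5.2156 -1.9282 -3.4677 -4.2838 0.2932 -5.5999 -2.4631 -5.1404 17.2219 -0.1495 -6.2804
Y -3.5061 -4.2232 -2.0789 -4.3384 0.3319 -4.0511 -4.2982 -5.2708 -0.0901 -1.0004 -0.9305 -4.4693 -2.4955 6.9751 -4.9593 -2.8541 -2.7775 -0.1495 10.1747 -2.5040
V 0.1942 -2.5279 -1.7729 -2.1492 -1.9399 -1.8880 -1.8124 -1.3494 -2.2665 3.7087 1.8506 -2.4672 1.7919 -1.1811 -1.2210 -0.9864 0.2837 -6.2804 -2.5040 4.3413
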