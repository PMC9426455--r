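ATOM      1  CA  ALA A   1       0.021   0.944  -0.022  1.00  0.00           C
ATOM      2  CA  ALA A   2       3.292  -0.947  -0.022  1.00  0.00           C
ATOM      3  CA  ALA A   3       6.605   0.959   0.002  1.00  0.00           C
ATOM      4  CA  ALA A   4       9.909  -0.929  -0.015  1.00  0.00           C
ATOM      5  CA  ALA A   5      13.206   0.939  -0.000  1.00  0.00           C
ATOM      6  CA  ALA A   6      16.498  -0.930  -0.006  1.00  0.00           C
ATOM      7  CA  ALA A   7      19.823   0.955  -0.009  1.00  0.00           C
ATOM      8  CA  ALA A   8      23.099  -0.934  -0.030  1.00  0.00           C
ATOM      9  CA  ALA A   9      26.430   0.964  -0.018  1.00  0.00           C
ATOM     10  CA  ALA A  10      30.031   0.961  -0.616  1.00  0.00           C
ATOM     11  CA  ALA A  11      31.969   0.934   2.477  1.00  0.00           C
ATOM     12  CA  ALA A  12      29.910   0.949   5.490  1.00  0.00           C
ATOM     13  CA  ALA A  13      26.327   0.960   4.790  1.00  0.00           C
ATOM     14  CA  ALA A  14      23.096  -0.964   4.817  1.00  0.00           C
ATOM     15  CA  ALA A  15      19.798   0.942   4.822  1.00  0.00           C
ATOM     16  CA  ALA A  16      16.510  -0.941   4.784  1.00  0.00           C
ATOM     17  CA  ALA A  17      13.196   0.962   4.798  1.00  0.00           C
ATOM     18  CA  ALA A  18       9.860  -0.943   4.818  1.00  0.00           C
ATOM     19  CA  ALA A  19       6.563   0.937   4.793  1.00  0.00           C
ATOM     20  CA  ALA A  20       3.320  -0.966   4.799  1.00  0.00           C
ATOM     21  CA  ALA A  21      -0.005   0.973   4.799  1.00  0.00           C
ATOM     22  CA  ALA A  22      -3.327  -0.946   4.787  1.00  0.00           C
ATOM     23  CA  ALA A  23      -6.603   0.951   4.793  1.00  0.00           C
ATOM     24  CA  ALA A  24      -9.882  -0.952   4.800  1.00  0.00           C
ATOM     25  CA  ALA A  25     -13.038  -1.664   3.035  1.00  0.00           C
ATOM     26  CA  ALA A  26     -16.590  -1.229   4.088  1.00  0.00           C
ATOM     27  CA  ALA A  27     -18.098  -0.003   7.193  1.00  0.00           C
ATOM     28  CA  ALA A  28     -16.610   1.236  10.322  1.00  0.00           C
ATOM     29  CA  ALA A  29     -13.059   1.660  11.369  1.00  0.00           C
ATOM     30  CA  ALA A  30      -9.910   0.962   9.584  1.00  0.00           C
ATOM     31  CA  ALA A  31      -6.593  -0.929   9.599  1.00  0.00           C
ATOM     32  CA  ALA A  32      -3.289   0.943   9.577  1.00  0.00           C
ATOM     33  CA  ALA A  33       0.016  -0.940   9.618  1.00  0.00           C
ATOM     34  CA  ALA A  34       3.291   0.971   9.596  1.00  0.00           C
ATOM     35  CA  ALA A  35       6.608  -0.967   9.593  1.00  0.00           C
ATOM     36  CA  ALA A  36       9.874   0.937   9.581  1.00  0.00           C
ATOM     37  CA  ALA A  37      13.188  -0.967   9.600  1.00  0.00           C
ATOM     38  CA  ALA A  38      16.596  -1.455   8.367  1.00  0.00           C
ATOM     39  CA  ALA A  39      19.592  -0.669  10.299  1.00  0.00           C
ATOM     40  CA  ALA A  40      19.621   0.682  13.718  1.00  0.00           C
ATOM     41  CA  ALA A  41      16.605   1.453  15.623  1.00  0.00           C
ATOM     42  CA  ALA A  42      13.195   0.966  14.384  1.00  0.00           C
ATOM     43  CA  ALA A  43       9.911  -0.965  14.402  1.00  0.00           C
ATOM     44  CA  ALA A  44       6.589   0.978  14.395  1.00  0.00           C
ATOM     45  CA  ALA A  45       3.279  -0.960  14.409  1.00  0.00           C
ATOM     46  CA  ALA A  46       0.006   0.952  14.421  1.00  0.00           C
ATOM     47  CA  ALA A  47      -3.312  -0.956  14.385  1.00  0.00           C
ATOM     48  CA  ALA A  48      -6.578   0.948  14.407  1.00  0.00           C
ATOM     49  CA  ALA A  49      -9.906  -0.947  14.401  1.00  0.00           C
ATOM     50  CA  ALA A  50     -13.190   0.952  14.413  1.00  0.00           C
ATOM     51  CA  ALA A  51     -16.495  -0.950  14.397  1.00  0.00           C
ATOM     52  CA  ALA A  52     -19.812   0.952  14.413  1.00  0.00           C
ATOM     53  CA  ALA A  53     -23.402   0.942  13.754  1.00  0.00           C
ATOM     54  CA  ALA A  54     -25.319   0.942  16.861  1.00  0.00           C
ATOM     55  CA  ALA A  55     -23.287   0.925  19.893  1.00  0.00           C
ATOM     56  CA  ALA A  56     -19.707   0.945  19.180  1.00  0.00           C
ATOM     57  CA  ALA A  57     -16.490  -0.958  19.178  1.00  0.00           C
ATOM     58  CA  ALA A  58     -13.199   0.991  19.210  1.00  0.00           C
ATOM     59  CA  ALA A  59      -9.945  -0.970  19.207  1.00  0.00           C
ATOM     60  CA  ALA A  60      -6.596   0.952  19.200  1.00  0.00           C
END
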