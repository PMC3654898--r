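# Frozen published constants (generated once at build time; do not edit).
published_amyloid_potentials <- rbind(
  A = c(0.510, 0.814, 1.469, 1.056, 0.000, 0.814),
  C = c(0.000, -0.434, -0.021, -0.021, 0.000, -0.263),
  D = c(0.848, 0.848, 1.259, 0.000, 0.000, 0.606),
  E = c(0.639, 0.335, 0.135, 0.468, 1.294, -0.974),
  F = c(-0.060, -0.231, -0.833, -0.060, -0.806, -0.300),
  G = c(-0.007, 0.596, 1.422, 0.000, 0.000, 1.009),
  H = c(-0.386, 0.027, 0.000, 0.681, 0.000, 0.000),
  I = c(0.408, -0.137, 1.235, -1.225, -1.460, 0.580),
  K = c(0.080, 0.000, 0.000, 1.239, 0.000, 0.826),
  L = c(0.310, -0.103, 0.231, -0.252, 1.056, 0.310),
  M = c(-0.291, 0.255, 0.668, 0.000, 0.000, -0.491),
  N = c(-0.142, 0.685, 0.442, -0.688, 0.000, 0.029),
  P = c(0.000, 0.000, 0.000, 0.000, 0.000, 0.000),
  Q = c(0.340, -0.314, -0.165, 0.000, 0.996, -0.534),
  R = c(0.734, 0.000, 0.000, 0.000, 0.000, 0.000),
  S = c(-1.036, 0.602, 0.098, 1.259, 1.259, -0.171),
  T = c(0.829, -1.089, 0.000, 0.175, 1.244, 0.083),
  V = c(-0.014, -0.071, -1.191, 1.355, 0.000, -0.071),
  W = c(-0.413, 0.000, -0.546, -0.747, 0.413, 0.413),
  Y = c(-0.204, -0.353, 0.956, -0.283, -0.798, -0.112))
published_nonamyloid_potentials <- rbind(
  A = c(0.423, -0.070, 0.622, 0.927, 0.622, 0.757),
  C = c(0.000, 0.093, -0.320, 0.500, 0.000, 0.000),
  D = c(0.214, 0.718, 0.306, 0.548, 0.414, 0.306),
  E = c(-0.073, -0.206, -0.244, -0.021, 0.340, -0.874),
  F = c(-0.250, 0.054, -0.772, -0.492, -0.864, -0.359),
  G = c(0.710, 0.375, 0.879, 0.467, 1.528, 0.225),
  H = c(-0.165, 0.139, 0.382, 0.139, 0.382, 0.382),
  I = c(0.280, 0.108, 0.280, -0.866, -1.122, 0.038),
  K = c(-0.370, 0.285, 0.192, 0.393, 0.285, 0.393),
  L = c(0.516, -0.031, 0.273, -0.423, 0.423, 0.011),
  M = c(0.126, -0.178, 0.369, 0.778, 0.778, -0.378),
  N = c(-0.028, 1.207, -0.270, -0.099, 0.251, 0.385),
  P = c(0.397, 0.566, 0.397, 0.262, 0.262, 0.262),
  Q = c(0.451, 0.451, 0.040, 0.282, 0.282, -0.052),
  R = c(-0.050, 0.604, 0.604, 0.300, 0.848, 0.192),
  S = c(-0.827, 0.132, 0.132, 0.303, 0.716, 0.061),
  T = c(0.117, -0.899, 0.530, 0.196, 0.942, -0.125),
  V = c(0.402, 0.310, -0.681, 0.645, 0.310, 0.645),
  W = c(-0.130, 0.114, -0.634, 0.521, 0.114, -0.130),
  Y = c(-0.240, -0.360, 0.413, -0.170, -0.503, 0.243))
colnames(published_amyloid_potentials) <- paste0("P", 1:6)
colnames(published_nonamyloid_potentials) <- paste0("P", 1:6)
published_globular_composition <- c(A = 8.47, C = 1.39, D = 5.97, E = 6.32, F = 3.91, G = 7.82, H = 2.26, I = 5.71, K = 5.76, L = 8.48, M = 2.21, N = 4.54, P = 4.63, Q = 3.82, R = 4.93, S = 5.94, T = 5.79, V = 7.02, W = 1.44, Y = 3.58)
published_mant_hydrophobicity <- c(A = 13.26, C = 26.84, D = 8.15, E = 11.12, F = 90.17, G = 3.80, H = 4.14, I = 69.53, K = 2.92, L = 73.84, M = 51.64, N = 1.00, P = 27.54, Q = 6.00, R = 10.24, S = 3.53, T = 11.64, V = 44.60, W = 100.00, Y = 47.49)
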