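#ifndef IP3R_MODEL_RATES_H
#define IP3R_MODEL_RATES_H

// Twelve-state IP3R generator assembled from occupancy (K) and flux (j)
// parameters at ligand condition (C, I) in uM.  Mirrors the R builder in
// R/generator.R; state order is canonical (open first):
//   0 O14I, 1 O24I, 2 O24H, 3 C00L, 4 C20L, 5 C30L, 6 C32L, 7 C34L,
//   8 C04L, 9 C04I, 10 C24I, 11 C24H
// K is passed in this canonical state order; j in the order of
// flux_params():
//   0 j0414, 1 j1424, 2 j2434, 3 j0414IL, 4 j1424IL, 5 j2434IL, 6 j2030,
//   7 j0414II, 8 j2424II, 9 j2424, 10 j0404, 11 j2424HH, 12 j3132,
//   13 j3334, 14 j0001, 15 j0304, 16 j2021, 17 j2324
// Rates in ms^-1.  IEEE division handles zero-ligand edge cases: a zero
// step rate blocks a composite pathway, an infinite one drops out.

namespace ip3r {

enum StateIdx { O14I = 0, O24I, O24H, C00L, C20L, C30L, C32L, C34L,
                C04L, C04I, C24I, C24H };

inline double rsr2(double a, double b) {
  return 1.0 / (1.0 / a + 1.0 / b);
}
inline double rsr3(double a, double b, double c) {
  return 1.0 / (1.0 / a + 1.0 / b + 1.0 / c);
}

// Fills Q (12x12, row-major Q[12*i + j]) and the diagonal.
inline void build_generator(const double *K, const double *j,
                            double C, double I, double *Q) {
  for (int k = 0; k < 144; ++k) Q[k] = 0.0;
  const double I3 = I * I * I, I4 = I3 * I;

  const double r0424f = rsr2(j[0] * C, j[1] * C * C);
  const double r0424b = rsr2(j[0] / C, j[1]);

  #define SET(a, b, f, w) do { Q[12 * (a) + (b)] = (f); Q[12 * (b) + (a)] = (w); } while (0)
  SET(C04I, C24H, r0424f / K[C04I], r0424b / K[C24H]);
  SET(C24H, O24H, j[11] / K[C24H], j[11] / K[O24H]);
  SET(O24H, C34L, j[2] * C / K[O24H], j[2] / K[C34L]);
  SET(C04I, C34L,
      rsr3(j[3] * C, j[4] * C * C, j[5] * C * C * C) / K[C04I],
      rsr3(j[3] / (C * C), j[4] / C, j[5]) / K[C34L]);
  SET(C04I, O14I, j[7] * C / K[C04I], j[7] / K[O14I]);
  SET(C24I, O24I, j[8] / K[C24I], j[8] / K[O24I]);
  SET(O24I, O24H, j[9] / K[O24I], j[9] / K[O24H]);
  SET(C04I, C04L, j[10] / K[C04I], j[10] / K[C04L]);
  SET(C32L, C34L, j[13] * I * I / K[C32L], j[13] / K[C34L]);
  SET(C30L, C32L, j[12] * I * I / K[C30L], j[12] / K[C32L]);
  SET(C20L, C30L, j[6] * C / K[C20L], j[6] / K[C30L]);
  SET(C00L, C04I, rsr2(j[14] * I, j[15] * I4),
      rsr2(j[14] / I3, j[15]) / K[C04I]);
  SET(C20L, C24H, rsr2(j[16] * I, j[17] * I4),
      rsr2(j[16] / I3, j[17]) * K[C20L] / K[C24H]);
  SET(C04I, C24I, r0424f / K[C04I], r0424b / K[C24I]);
  SET(C00L, C20L, r0424f / K[C04I], r0424b / (K[C04I] * K[C20L]));
  #undef SET

  for (int a = 0; a < 12; ++a) {
    double s = 0.0;
    for (int b = 0; b < 12; ++b) if (b != a) s += Q[12 * a + b];
    Q[12 * a + a] = -s;
  }
}

}  // namespace ip3r

#endif
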