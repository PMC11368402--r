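#include <Rcpp.h>
using namespace Rcpp;

// One generation of the SSI forward model. Haplotypes are (S-allele index,
// D-vector); S- and D-locus are fully linked. For each offspring slot:
// mother uniform; father uniform, redrawn until the father's sporophytic
// pollen phenotype shares no specificity with the mother's pistil
// phenotype; each parent transmits one haplotype uniformly with
// per-position mutation; the zygote survives with probability
// (1-s)^n_hom, otherwise the whole mating is redrawn. Uses the R RNG.

static inline int unif_int(int n) { return (int) R_unif_index((double) n); }

// expressed pollen alleles of individual i: dominant class masks the other;
// same class (distinct alleles) -> both. e2 = -1 when single.
static inline void expressed(int a1, int a2, const IntegerVector& cls,
                             int& e1, int& e2) {
  int c1 = cls[a1], c2 = cls[a2];
  if (a1 == a2)      { e1 = a1; e2 = -1; }
  else if (c1 > c2)  { e1 = a1; e2 = -1; }
  else if (c2 > c1)  { e1 = a2; e2 = -1; }
  else               { e1 = a1; e2 = a2; }
}

static inline bool shares(int fe1, int fe2, int me1, int me2) {
  if (fe1 == me1 || (me2 >= 0 && fe1 == me2)) return true;
  if (fe2 >= 0 && (fe2 == me1 || (me2 >= 0 && fe2 == me2))) return true;
  return false;
}

// [[Rcpp::export(name = ".step_generation_cpp")]]
List step_generation_cpp(IntegerVector s1, IntegerVector s2,
                         LogicalMatrix d1, LogicalMatrix d2,
                         IntegerVector cls0,   // class per allele, 1-based roster
                         double mu_f, double mu_b, double s,
                         bool pistil_dominance, int max_father_draws) {
  const int N = s1.size(), L = d1.ncol();
  IntegerVector cls = cls0;  // indexed by 0-based allele id
  IntegerVector os1(N), os2(N);
  LogicalMatrix od1(N, L), od2(N, L);
  std::vector<int> pe1(N), pe2(N), me1(N), me2(N);
  for (int i = 0; i < N; ++i) {
    expressed(s1[i] - 1, s2[i] - 1, cls, pe1[i], pe2[i]);
    if (pistil_dominance) { me1[i] = pe1[i]; me2[i] = pe2[i]; }
    else {
      me1[i] = s1[i] - 1;
      me2[i] = (s1[i] == s2[i]) ? -1 : s2[i] - 1;
    }
  }
  std::vector<int> gm(L), gf(L);
  for (int slot = 0; slot < N; ++slot) {
    for (;;) {                       // mating attempts (survival rejection)
      int mo = unif_int(N);
      int fa = -1, tries = 0;
      for (;;) {                     // father rejection on compatibility
        int cand = unif_int(N);
        if (!shares(pe1[cand], pe2[cand], me1[mo], me2[mo])) { fa = cand; break; }
        if (++tries > max_father_draws)
          stop("no SSI-compatible father found after %d draws", max_father_draws);
      }
      int mh = unif_int(2), fh = unif_int(2);
      int sa_m = mh == 0 ? s1[mo] : s2[mo];
      int sa_f = fh == 0 ? s1[fa] : s2[fa];
      int nhom = 0;
      for (int j = 0; j < L; ++j) {
        bool a = mh == 0 ? d1(mo, j) : d2(mo, j);
        double u = unif_rand();
        a = a ? (u >= mu_b) : (u < mu_f);
        bool b = fh == 0 ? d1(fa, j) : d2(fa, j);
        u = unif_rand();
        b = b ? (u >= mu_b) : (u < mu_f);
        gm[j] = a; gf[j] = b;
        if (a && b) ++nhom;
      }
      double p = std::pow(1.0 - s, (double) nhom);
      if (nhom == 0 || unif_rand() < p) {
        os1[slot] = sa_m; os2[slot] = sa_f;
        for (int j = 0; j < L; ++j) { od1(slot, j) = gm[j]; od2(slot, j) = gf[j]; }
        break;
      }
      // zygote died: redraw the whole mating
    }
  }
  return List::create(_["s1"] = os1, _["s2"] = os2,
                      _["d1"] = od1, _["d2"] = od2);
}
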