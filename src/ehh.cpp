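#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity machinery.
//
// EHH over an inclusive span of sites is sum_g C(m_g,2) / C(m,2), where the
// m haplotypes partition into groups g identical over the span. iHH is the
// trapezoidal integral of the EHH decay curve over physical distance,
// extended outward from the core in both directions and truncated at the
// first site whose EHH falls below `cutoff` (that segment is not added).
// Partition refinement makes each outward step O(haplotypes).

static inline double ehh_from_counts(const std::vector<int>& cnt, double denom) {
    double s = 0.0;
    for (size_t g = 0; g < cnt.size(); ++g)
        s += cnt[g] * (cnt[g] - 1.0) / 2.0;
    return s / denom;
}

// refine partition `grp` (group ids 0..ngroups-1) by alleles at one site;
// returns new number of groups, updates grp and cnt
static int refine(std::vector<int>& grp, std::vector<int>& cnt,
                  const int* alleles, int H, int ngroups) {
    std::vector<int> remap(2 * ngroups, -1);
    std::vector<int> newcnt;
    newcnt.reserve(ngroups + 4);
    int nnew = 0;
    for (int i = 0; i < H; ++i) {
        int key = grp[i] * 2 + (alleles[i] != 0);
        if (remap[key] < 0) {
            remap[key] = nnew++;
            newcnt.push_back(0);
        }
        grp[i] = remap[key];
        newcnt[grp[i]]++;
    }
    cnt.swap(newcnt);
    return nnew;
}

// iHH at every core site for one chromosome of pooled haplotypes.
// haps: H x L 0/1 matrix; pos: physical positions (ascending).
// Returns a vector of iHH values (0 when the curve never extends).
// [[Rcpp::export(name = ".ihh_all_cores")]]
NumericVector ihh_all_cores(IntegerMatrix haps, NumericVector pos,
                            double cutoff) {
    const int H = haps.nrow(), L = haps.ncol();
    if (H < 2) stop("need at least 2 haplotypes");
    const double denom = H * (H - 1.0) / 2.0;
    NumericVector out(L);

    // column-major access: alleles of site j are contiguous
    std::vector<int> col(H * L);
    for (int j = 0; j < L; ++j)
        for (int i = 0; i < H; ++i)
            col[j * H + i] = haps(i, j);

    std::vector<int> grp(H), cnt;
    for (int core = 0; core < L; ++core) {
        double ihh = 0.0;
        for (int dir = 0; dir < 2; ++dir) {
            // initialise partition with the core site itself
            std::fill(grp.begin(), grp.end(), 0);
            cnt.assign(1, H);
            int ngroups = refine(grp, cnt, &col[core * H], H, 1);
            double ehh_prev = ehh_from_counts(cnt, denom);
            if (ehh_prev < cutoff) continue;
            double pos_prev = pos[core];
            int j = core;
            while (true) {
                j += (dir == 0) ? -1 : 1;
                if (j < 0 || j >= L) break;
                ngroups = refine(grp, cnt, &col[j * H], H, ngroups);
                double ehh = ehh_from_counts(cnt, denom);
                if (ehh < cutoff) break;
                ihh += 0.5 * (ehh_prev + ehh) * std::abs(pos[j] - pos_prev);
                ehh_prev = ehh;
                pos_prev = pos[j];
                if (ngroups == H) {
                    // all singletons: EHH can only stay constant at its
                    // floor; if that floor is below cutoff we'd have broken
                    // already, but it equals 0 only when H groups of 1
                    if (ehh_from_counts(cnt, denom) <= 0.0) break;
                }
            }
        }
        out[core] = ihh;
    }
    return out;
}
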