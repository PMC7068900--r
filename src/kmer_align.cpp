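// Seed-based competitive alignment of long reads against a small set of
// junction contigs. Substitution-tolerant: exact k-mer seeds are matched
// against an index of each contig, votes are accumulated per diagonal
// band, and the best band yields an approximate local alignment (score =
// number of seed hits, extent = seeded span on the contig). Sufficient
// for breakpoint-orientation classification of reads with percent-scale
// substitution error; indel-heavy data should come in through the
// table-based adapter instead.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// k-mers as 2-bit packed uint64; positions of each k-mer in a contig
typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void index_contig(const std::string& seq, int k, int max_occ,
                         KmerIndex& idx) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)b) & mask;
    if (++run < k) continue;
    std::vector<int>& v = idx[cur];
    if ((int)v.size() <= max_occ) v.push_back((int)(i + 1 - k));
  }
  // drop over-represented (repeat) k-mers entirely
  for (KmerIndex::iterator it = idx.begin(); it != idx.end();) {
    if ((int)it->second.size() > max_occ) it = idx.erase(it);
    else ++it;
  }
}

struct Band {
  int hits = 0;
  int qmin = 0, qmax = 0, tmin = 0, tmax = 0;
};

// best diagonal band for one read orientation vs one indexed contig;
// bands live in a flat vector indexed by shifted diagonal
static Band best_band(const std::string& read, int k, int step,
                      const KmerIndex& idx, int bandwidth,
                      int contig_len, std::vector<Band>& bands) {
  int qlen = (int)read.size();
  int nb = (contig_len + qlen) / bandwidth + 3;
  if ((int)bands.size() < nb) bands.resize(nb);
  for (int i = 0; i < nb; ++i) bands[i].hits = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    int b = base2bits(read[i]);
    if (b < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)b) & mask;
    if (++run < k) continue;
    int q = (int)(i + 1 - k);
    if (q % step != 0) continue;
    KmerIndex::const_iterator hit = idx.find(cur);
    if (hit == idx.end()) continue;
    for (size_t m = 0; m < hit->second.size(); ++m) {
      int t = hit->second[m];
      int band = (t - q + qlen) / bandwidth;
      Band& bd = bands[band];
      if (bd.hits == 0) {
        bd.qmin = bd.qmax = q; bd.tmin = bd.tmax = t;
      } else {
        if (q < bd.qmin) bd.qmin = q;
        if (q > bd.qmax) bd.qmax = q;
        if (t < bd.tmin) bd.tmin = t;
        if (t > bd.tmax) bd.tmax = t;
      }
      bd.hits++;
    }
  }
  // merge each band with its right neighbor so hits straddling a band
  // boundary are not split
  Band best;
  for (int i = 0; i < nb; ++i) {
    if (bands[i].hits == 0) continue;
    Band merged = bands[i];
    if (i + 1 < nb && bands[i + 1].hits > 0) {
      const Band& o = bands[i + 1];
      merged.hits += o.hits;
      if (o.qmin < merged.qmin) merged.qmin = o.qmin;
      if (o.qmax > merged.qmax) merged.qmax = o.qmax;
      if (o.tmin < merged.tmin) merged.tmin = o.tmin;
      if (o.tmax > merged.tmax) merged.tmax = o.tmax;
    }
    if (merged.hits > best.hits) best = merged;
  }
  return best;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': case 'a': r[i] = 'T'; break;
      case 'C': case 'c': r[i] = 'G'; break;
      case 'G': case 'g': r[i] = 'C'; break;
      case 'T': case 't': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

// [[Rcpp::export(name = ".kmer_align_cpp")]]
DataFrame kmer_align_cpp(CharacterVector reads, CharacterVector contigs,
                         int k = 15, int step = 3, int max_occ = 8,
                         int bandwidth = 64) {
  int nc = contigs.size();
  std::vector<KmerIndex> indexes(nc);
  std::vector<int> contig_lens(nc);
  for (int c = 0; c < nc; ++c) {
    std::string cs = as<std::string>(contigs[c]);
    contig_lens[c] = (int)cs.size();
    index_contig(cs, k, max_occ, indexes[c]);
  }

  std::vector<int> out_read, out_contig, out_score;
  std::vector<int> out_qs, out_qe, out_ts, out_te;
  std::vector<std::string> out_strand;
  std::vector<Band> scratch;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp_str(fwd);
    int L = (int)fwd.size();
    for (int c = 0; c < nc; ++c) {
      Band bf = best_band(fwd, k, step, indexes[c], bandwidth,
                          contig_lens[c], scratch);
      Band br = best_band(rev, k, step, indexes[c], bandwidth,
                          contig_lens[c], scratch);
      bool use_rev = br.hits > bf.hits;
      const Band& b = use_rev ? br : bf;
      if (b.hits == 0) continue;
      int qs = b.qmin, qe = b.qmax + k;
      if (use_rev) { // report read coordinates on the forward read
        int nqs = L - qe, nqe = L - qs;
        qs = nqs; qe = nqe;
      }
      out_read.push_back(r + 1);
      out_contig.push_back(c + 1);
      out_score.push_back(b.hits);
      out_qs.push_back(qs);
      out_qe.push_back(qe);
      out_ts.push_back(b.tmin);
      out_te.push_back(b.tmax + k);
      out_strand.push_back(use_rev ? "-" : "+");
    }
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["read"] = out_read, _["contig"] = out_contig,
    _["score"] = out_score, _["qstart"] = out_qs, _["qend"] = out_qe,
    _["tstart"] = out_ts, _["tend"] = out_te, _["strand"] = out_strand,
    _["stringsAsFactors"] = false);
}
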