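// Depth-first enumeration of sum-over-trips paths with a physical-length
// cutoff.  The continuation table is precompiled in R (one entry per
// (node, in-branch) state); here we only walk it, emitting every trip whose
// total length stays within the cutoff.  The admissibility pruning uses the
// precomputed shortest remaining distance to the target point, so the search
// visits essentially only the trips it reports.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

struct Cont {
  std::vector<int> fidx;         // factor index (1-based), per continuation
  std::vector<double> term_cost; // cost to terminate at y (<0: none)
  std::vector<double> term_len;  // physical length of that final piece
  std::vector<int> far_state;    // successor state (0: none)
  std::vector<double> far_cost;  // traversal cost to the far node
  std::vector<double> far_len;   // physical branch length to the far node
  std::vector<double> far_min;   // cheapest remaining cost from far node
  std::vector<int> ocl;          // parameter class of the out branch (1-based)
};

struct Acc {
  std::vector<double> len;       // total trip costs
  std::vector<double> lbc;       // ntrips x nclass, row-major
  std::vector<int> fac_concat;   // concatenated factor sequences
  std::vector<int> fac_n;        // events per trip
  std::vector<double> cnt;       // ntrips x nfac, row-major
  std::vector<int> start;        // departure id per trip (0 = direct)
  int nclass, nfac, cur_start;
};

void emit(Acc &acc, double total, const std::vector<int> &fac,
          const std::vector<double> &lb) {
  acc.len.push_back(total);
  acc.start.push_back(acc.cur_start);
  acc.lbc.insert(acc.lbc.end(), lb.begin(), lb.end());
  acc.fac_concat.insert(acc.fac_concat.end(), fac.begin(), fac.end());
  acc.fac_n.push_back((int)fac.size());
  std::vector<double> row(acc.nfac, 0.0);
  for (int f : fac) row[f - 1] += 1.0;
  acc.cnt.insert(acc.cnt.end(), row.begin(), row.end());
}

bool walk(const std::vector<Cont> &cont, double cutoff, Acc &acc, int s,
          double cost, std::vector<int> &fac, std::vector<double> &lb,
          int max_trips) {
  const Cont &co = cont[s - 1];
  for (size_t k = 0; k < co.fidx.size(); ++k) {
    double tc = co.term_cost[k];
    int cl = co.ocl[k] - 1;
    if (tc >= 0.0 && cost + tc <= cutoff) {
      if ((int)acc.len.size() >= max_trips) return false;
      fac.push_back(co.fidx[k]);
      lb[cl] += co.term_len[k];
      emit(acc, cost + tc, fac, lb);
      lb[cl] -= co.term_len[k];
      fac.pop_back();
    }
    int fs = co.far_state[k];
    if (fs > 0) {
      double nc = cost + co.far_cost[k];
      if (nc + co.far_min[k] <= cutoff) {
        fac.push_back(co.fidx[k]);
        lb[cl] += co.far_len[k];
        bool ok = walk(cont, cutoff, acc, fs, nc, fac, lb, max_trips);
        lb[cl] -= co.far_len[k];
        fac.pop_back();
        if (!ok) return false;
      }
    }
  }
  return true;
}

} // namespace

// [[Rcpp::export]]
List enum_trips_cpp(List cont_list, List starts, double cutoff, int nclass,
                    int nfac, double direct_cost, double direct_len,
                    int direct_class, int max_trips) {
  std::vector<Cont> cont(cont_list.size());
  for (int s = 0; s < cont_list.size(); ++s) {
    List c = cont_list[s];
    cont[s].fidx = as<std::vector<int>>(c["fidx"]);
    cont[s].term_cost = as<std::vector<double>>(c["term_cost"]);
    cont[s].term_len = as<std::vector<double>>(c["term_len"]);
    cont[s].far_state = as<std::vector<int>>(c["far_state"]);
    cont[s].far_cost = as<std::vector<double>>(c["far_cost"]);
    cont[s].far_len = as<std::vector<double>>(c["far_len"]);
    cont[s].far_min = as<std::vector<double>>(c["far_min"]);
    cont[s].ocl = as<std::vector<int>>(c["ocl"]);
  }

  Acc acc;
  acc.nclass = nclass;
  acc.nfac = nfac;

  std::vector<int> fac;
  std::vector<double> lb(nclass, 0.0);
  bool ok = true;

  // direct trip (x and y on the same branch), if admissible
  acc.cur_start = 0;
  if (direct_class > 0 && direct_cost <= cutoff) {
    lb[direct_class - 1] = direct_len;
    emit(acc, direct_cost, fac, lb);
    lb[direct_class - 1] = 0.0;
  }

  for (int i = 0; i < starts.size() && ok; ++i) {
    List st = starts[i];
    int s = as<int>(st["state"]);
    double d0c = as<double>(st["d0_cost"]);
    double d0 = as<double>(st["d0"]);
    int cl = as<int>(st["cl"]);
    acc.cur_start = as<int>(st["id"]);
    lb[cl - 1] = d0;
    ok = walk(cont, cutoff, acc, s, d0c, fac, lb, max_trips);
    lb[cl - 1] = 0.0;
  }

  int ntr = (int)acc.len.size();
  NumericMatrix Lmat(ntr, nclass), Fcount(ntr, nfac);
  for (int i = 0; i < ntr; ++i) {
    for (int j = 0; j < nclass; ++j) Lmat(i, j) = acc.lbc[(size_t)i * nclass + j];
    for (int j = 0; j < nfac; ++j) Fcount(i, j) = acc.cnt[(size_t)i * nfac + j];
  }
  return List::create(_["costs"] = wrap(acc.len),
                      _["Lmat"] = Lmat, _["Fcount"] = Fcount,
                      _["fac_concat"] = wrap(acc.fac_concat),
                      _["fac_n"] = wrap(acc.fac_n),
                      _["start"] = wrap(acc.start),
                      _["capped"] = !ok);
}
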