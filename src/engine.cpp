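#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Multicellular stochastic engine. One cell = biomass plus parallel per-copy
// trait vectors (alpha, kappa, beta, neutral lineage label). Uses R's RNG
// throughout, so runs are reproducible from set.seed() on the R side.
//
// Update order within a step (fixed for reproducibility):
//   grow -> replicate/mutate -> death check -> division check -> regulate.
// Daughters enter the schedule at the next step.

namespace {

struct Cell {
    double mass;
    double sumk = 0;     // cached sum of kappa over copies
    bool homog = true;   // cached: all copies share one genotype and label
    std::vector<double> a, k, b, lab;
    size_t n() const { return a.size(); }
    void refreshCache() {
        sumk = 0;
        homog = true;
        for (size_t j = 0; j < a.size(); ++j) {
            sumk += k[j];
            if (a[j] != a[0] || k[j] != k[0] || b[j] != b[0] ||
                lab[j] != lab[0])
                homog = false;
        }
    }
    void addCopy(double av, double kv, double bv, double lv) {
        if (!a.empty() &&
            (av != a[0] || kv != k[0] || bv != b[0] || lv != lab[0]))
            homog = false;
        sumk += kv;
        a.push_back(av); k.push_back(kv); b.push_back(bv); lab.push_back(lv);
    }
};

struct EvoPars {
    double mu, step;
    double bounds[3];
    bool free_[3];
    int nFree;
};

inline double clip(double x, double hi) {
    return x < 0 ? 0 : (x > hi ? hi : x);
}

// perturb exactly one trait, chosen uniformly among the free ones
inline void mutateTraits(double* tr, const EvoPars& ev) {
    if (ev.nFree == 0) return;
    int pick = (int)std::floor(unif_rand() * ev.nFree);
    if (pick >= ev.nFree) pick = ev.nFree - 1;
    int idx = -1;
    for (int t = 0; t < 3; ++t) {
        if (ev.free_[t] && ++idx == pick) {
            double half = ev.step * ev.bounds[t];
            tr[t] = clip(tr[t] + (2.0 * unif_rand() - 1.0) * half,
                         ev.bounds[t]);
            return;
        }
    }
}

inline void pushCopy(Cell& c, double a, double k, double b, double lab,
                     const EvoPars& ev) {
    double tr[3] = {a, k, b};
    if (ev.mu > 0 && unif_rand() < ev.mu) mutateTraits(tr, ev);
    c.addCopy(tr[0], tr[1], tr[2], lab);
}

} // namespace

// [[Rcpp::export(name = ".engineRun")]]
List engineRun(NumericVector mass0, NumericMatrix plasmids0,
               IntegerVector cellOf, List cellPars, List evoPars,
               int cap, int steps, int recordEvery, int histFrom,
               int histMax) {
    const double g0 = cellPars["g0"], B = cellPars["B"],
                 s = cellPars["steepness"], cc = cellPars["c"],
                 cInh = cellPars["cInh"], M0 = cellPars["M0"],
                 tau = cellPars["tau"], dt = cellPars["dt"];
    EvoPars ev;
    ev.mu = as<double>(evoPars["mu"]);
    ev.step = as<double>(evoPars["step"]);
    NumericVector bnd = evoPars["bounds"];
    LogicalVector fr = evoPars["free"];
    ev.nFree = 0;
    for (int t = 0; t < 3; ++t) {
        ev.bounds[t] = bnd[t];
        ev.free_[t] = fr[t];
        if (ev.free_[t]) ++ev.nFree;
    }

    std::vector<Cell> cells(mass0.size());
    for (int i = 0; i < mass0.size(); ++i) cells[i].mass = mass0[i];
    for (int j = 0; j < plasmids0.nrow(); ++j) {
        Cell& c = cells[cellOf[j] - 1];
        c.addCopy(plasmids0(j, 0), plasmids0(j, 1), plasmids0(j, 2),
                  plasmids0(j, 3));
    }

    double counters[4] = {0, 0, 0, 0};  // divisions, deaths, segLoss, divInf
    double interval[4] = {0, 0, 0, 0};
    std::vector<double> hist(histMax, 0.0);

    const int nRec = steps / recordEvery + 1;
    const int NCOL = 20;
    NumericMatrix series(nRec, NCOL);
    int recRow = 0;
    bool terminated = false;

    GetRNGstate();

    auto record = [&](int step) {
        if (recRow >= nRec) return;
        double t = step * dt;
        int pop = (int)cells.size(), inf = 0;
        double sn = 0, sn2 = 0, sn3 = 0;
        double sTr[3] = {0, 0, 0};
        long totCopies = 0;
        double sWithin[3] = {0, 0, 0};
        std::vector<double> hm[3];
        for (const Cell& c : cells) {
            size_t n = c.n();
            if (n == 0) continue;
            ++inf;
            totCopies += n;
            sn += n;
            if (step >= histFrom) {
                int bin = (int)n;
                if (bin > histMax) bin = histMax;
                hist[bin - 1] += 1;
            }
            const std::vector<double>* tv[3] = {&c.a, &c.k, &c.b};
            for (int t3 = 0; t3 < 3; ++t3) {
                double m = 0;
                for (double v : *(tv[t3])) m += v;
                sTr[t3] += m;
                m /= n;
                hm[t3].push_back(m);
                double v2 = 0;
                for (double v : *(tv[t3])) v2 += (v - m) * (v - m);
                sWithin[t3] += std::sqrt(v2 / n);
            }
        }
        int col = 0;
        series(recRow, col++) = t;
        series(recRow, col++) = pop;
        series(recRow, col++) = inf;
        for (int e = 0; e < 4; ++e) {
            series(recRow, col++) = interval[e];
            interval[e] = 0;
        }
        // copy-number moments over infected cells
        double meanN = NA_REAL, sdN = NA_REAL, skN = NA_REAL;
        if (inf > 0) {
            meanN = sn / inf;
            for (const Cell& c : cells) {
                if (c.n() == 0) continue;
                double d = (double)c.n() - meanN;
                sn2 += d * d;
                sn3 += d * d * d;
            }
            double m2 = sn2 / inf;
            sdN = std::sqrt(m2);
            skN = m2 > 0 ? (sn3 / inf) / std::pow(m2, 1.5) : NA_REAL;
        }
        series(recRow, col++) = meanN;
        series(recRow, col++) = sdN;
        series(recRow, col++) = skN;
        for (int t3 = 0; t3 < 3; ++t3) {
            series(recRow, col++) =
                totCopies ? sTr[t3] / totCopies : NA_REAL;
        }
        for (int t3 = 0; t3 < 3; ++t3) {
            series(recRow, col++) = inf ? sWithin[t3] / inf : NA_REAL;
            double btw = NA_REAL;
            if (inf > 1) {
                double m = 0;
                for (double v : hm[t3]) m += v;
                m /= inf;
                double v2 = 0;
                for (double v : hm[t3]) v2 += (v - m) * (v - m);
                btw = std::sqrt(v2 / inf);
            }
            series(recRow, col++) = btw;
        }
        // plasmid-weighted mean lineage label (type frequency in competitions)
        double slab = 0;
        for (const Cell& c : cells)
            for (double v : c.lab) slab += v;
        series(recRow, col++) = totCopies ? slab / totCopies : NA_REAL;
        ++recRow;
    };

    record(0);

    std::vector<double> rs;   // reusable per-cell rate buffer
    for (int step = 1; step <= steps; ++step) {
        std::vector<Cell> next;
        next.reserve(cells.size() + 16);
        for (Cell& c : cells) {
            size_t n = c.n();
            double g = g0 + B * (1.0 - std::exp(-s * (double)n)) -
                       cc * (double)n - cInh * c.sumk;
            c.mass *= 1.0 + g * dt;
            if (c.mass > 0 && n > 0) {
                double I = tau * c.sumk / c.mass;
                if (c.homog) {
                    double r = c.a[0] / (1.0 + c.b[0] * I);
                    int m = (int)R::rpois((double)n * r * dt);
                    for (int j = 0; j < m; ++j)
                        pushCopy(c, c.a[0], c.k[0], c.b[0], c.lab[0], ev);
                } else {
                    // one Poisson draw for the cell's summed replication
                    // rate, each event assigned to a plasmid proportionally
                    // to its own rate: distributionally identical to
                    // independent per-plasmid Poisson draws
                    rs.resize(n);
                    double tot = 0;
                    for (size_t j = 0; j < n; ++j) {
                        rs[j] = c.a[j] / (1.0 + c.b[j] * I);
                        tot += rs[j];
                    }
                    int m = tot > 0 ? (int)R::rpois(tot * dt) : 0;
                    for (int q = 0; q < m; ++q) {
                        double u = unif_rand() * tot, acc = 0;
                        size_t j = 0;
                        for (; j + 1 < n; ++j) {
                            acc += rs[j];
                            if (u <= acc) break;
                        }
                        pushCopy(c, c.a[j], c.k[j], c.b[j], c.lab[j], ev);
                    }
                }
            }
            // Copy number never decreases within a cell's life, so g is
            // non-increasing and a cell that has shrunk to half the newborn
            // biomass can never grow back: it is dead. (The multiplicative
            // update cannot cross zero while -1 < g*dt < 0, so waiting for
            // negative biomass would leave perpetually shrinking cells.)
            if (c.mass <= 0.5 * M0) {
                counters[1] += 1; interval[1] += 1;  // death
                continue;
            }
            if (c.mass >= 2.0 * M0) {
                size_t nn = c.n();
                counters[0] += 1; interval[0] += 1;
                bool infected = nn > 0;
                if (infected) { counters[3] += 1; interval[3] += 1; }
                Cell d1, d2;
                d1.mass = d2.mass = c.mass / 2.0;
                for (size_t j = 0; j < nn; ++j) {
                    Cell& d = (unif_rand() < 0.5) ? d1 : d2;
                    d.addCopy(c.a[j], c.k[j], c.b[j], c.lab[j]);
                }
                if (infected && (d1.n() == 0 || d2.n() == 0)) {
                    counters[2] += 1; interval[2] += 1;
                }
                next.push_back(std::move(d1));
                next.push_back(std::move(d2));
            } else {
                next.push_back(std::move(c));
            }
        }
        // neutral regulation: uniform random culling down to cap
        while ((int)next.size() > cap) {
            size_t drop = (size_t)std::floor(unif_rand() * next.size());
            if (drop >= next.size()) drop = next.size() - 1;
            next[drop] = std::move(next.back());
            next.pop_back();
        }
        cells = std::move(next);
        if (cells.empty()) {
            record(step);
            terminated = true;
            break;
        }
        if (step % recordEvery == 0) record(step);
    }

    PutRNGstate();

    // final population state
    long totCopies = 0;
    for (const Cell& c : cells) totCopies += c.n();
    NumericVector fmass(cells.size());
    NumericMatrix fpl(totCopies, 4);
    IntegerVector fcell(totCopies);
    long row = 0;
    for (size_t i = 0; i < cells.size(); ++i) {
        fmass[i] = cells[i].mass;
        for (size_t j = 0; j < cells[i].n(); ++j) {
            fpl(row, 0) = cells[i].a[j];
            fpl(row, 1) = cells[i].k[j];
            fpl(row, 2) = cells[i].b[j];
            fpl(row, 3) = cells[i].lab[j];
            fcell[row] = (int)i + 1;
            ++row;
        }
    }

    if (recRow < nRec) series = series(Range(0, recRow - 1), Range(0, NCOL - 1));
    colnames(series) = CharacterVector::create(
        "time", "popSize", "infected", "divisions", "deaths", "segLosses",
        "divisionsInfected", "meanN", "sdN", "skewN",
        "meanAlpha", "meanKappa", "meanBeta",
        "withinSdAlpha", "betweenSdAlpha", "withinSdKappa", "betweenSdKappa",
        "withinSdBeta", "betweenSdBeta", "meanLabel");

    return List::create(
        _["series"] = series,
        _["hist"] = NumericVector(hist.begin(), hist.end()),
        _["counters"] = NumericVector::create(
            _["divisions"] = counters[0], _["deaths"] = counters[1],
            _["segLosses"] = counters[2],
            _["divisionsInfected"] = counters[3]),
        _["mass"] = fmass, _["plasmids"] = fpl, _["cellOf"] = fcell,
        _["terminated"] = terminated);
}
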