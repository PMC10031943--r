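"""Independent coalescent oracle for the hybrid-founding scenario.

Simulates SNP panels with msprime under the same demography as the package's
scenario 1 (two parental species splitting from an ancestor, a hybrid-founded
population and an introgression-founded population), with one mutation per
locus placed on a branch chosen proportionally to branch length and pooled
minor-allele-frequency ascertainment. Writes one CSV row per panel: dosages
flattened individual-fastest (n_ind * n_loci integers).

Usage:
  python msprime_scenario1.py --out panels.csv --panels 2000 --loci 30 \
      --samples 10,10,10,10 --n1 7730 --n2 3300 --n3 1060 --n4 12500 \
      --na 8200 --t1 97.9 --t2 211 --t4 2000 --r1 0.33 --r2 0.68 \
      --maf 0.05 --seed 1
"""

import argparse

import msprime
import numpy as np


def build_demography(a):
    dem = msprime.Demography()
    dem.add_population(name="MIC", initial_size=a.n1)
    dem.add_population(name="PT", initial_size=a.n2)
    dem.add_population(name="NGL", initial_size=a.n3)
    dem.add_population(name="FLA", initial_size=a.n4)
    dem.add_population(name="ANC", initial_size=a.na)
    dem.add_admixture(time=a.t1, derived="NGL", ancestral=["MIC", "FLA"],
                      proportions=[a.r1, 1 - a.r1])
    dem.add_admixture(time=a.t2, derived="PT", ancestral=["MIC", "FLA"],
                      proportions=[a.r2, 1 - a.r2])
    dem.add_population_split(time=a.t4, derived=["MIC", "FLA"],
                             ancestral="ANC")
    dem.sort_events()
    return dem


def one_locus(ts, rng, maf_min):
    """Place one mutation branch-length-weighted; return per-individual
    dosages or None if the locus fails ascertainment."""
    tree = ts.first()
    nodes = [u for u in tree.nodes() if tree.parent(u) != -1]
    lengths = np.array([tree.branch_length(u) for u in nodes])
    u = nodes[rng.choice(len(nodes), p=lengths / lengths.sum())]
    carriers = list(tree.samples(u))
    n_hap = ts.num_samples
    c = len(carriers)
    if min(c, n_hap - c) < maf_min * n_hap:
        return None
    dos = np.zeros(n_hap // 2, dtype=int)
    node_ind = {n: ts.node(n).individual for n in ts.samples()}
    for n in carriers:
        dos[node_ind[n]] += 1
    return dos


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--out", required=True)
    ap.add_argument("--panels", type=int, default=2000)
    ap.add_argument("--loci", type=int, default=30)
    ap.add_argument("--samples", default="10,10,10,10")
    for nm, dv in [("n1", 7730.0), ("n2", 3300.0), ("n3", 1060.0),
                   ("n4", 12500.0), ("na", 8200.0), ("t1", 97.9),
                   ("t2", 211.0), ("t4", 2000.0), ("r1", 0.33),
                   ("r2", 0.68), ("maf", 0.05)]:
        ap.add_argument("--" + nm, type=float, default=dv)
    ap.add_argument("--seed", type=int, default=1)
    a = ap.parse_args()

    nm, npt, ng, nf = (int(x) for x in a.samples.split(","))
    dem = build_demography(a)
    samples = {"MIC": nm, "PT": npt, "NGL": ng, "FLA": nf}
    n_ind = nm + npt + ng + nf
    rng = np.random.default_rng(a.seed)

    with open(a.out, "w") as fh:
        for panel in range(a.panels):
            got = 0
            cols = np.zeros((n_ind, a.loci), dtype=int)
            while got < a.loci:
                todo = a.loci - got
                reps = msprime.sim_ancestry(
                    samples=samples, demography=dem, ploidy=2,
                    num_replicates=max(2 * todo, 8),
                    random_seed=int(rng.integers(1, 2**31 - 1)))
                for ts in reps:
                    dos = one_locus(ts, rng, a.maf)
                    if dos is None:
                        continue
                    cols[:, got] = dos
                    got += 1
                    if got == a.loci:
                        break
            fh.write(",".join(str(v) for v in cols.T.reshape(-1)) + "\n")


if __name__ == "__main__":
    main()
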