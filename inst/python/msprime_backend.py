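"""Coalescent simulation backend.

Reads a JSON job describing a batch of two-population demographies and
per-locus seeds, simulates each locus with msprime (coalescent with
recombination, infinite-sites mutations with known ancestral state), and
writes all loci to a single plain-text stream:

    L <sim_id> <locus_idx> <n_hap> <n_sites>
    P <pos1> <pos2> ...
    <haplotype row as 0/1 string>   (n_hap lines, population 1 first)

Time is in generations; population sizes are diploid.  Backward-time size
of descendant population i is N_i(t) = size_i * exp(-growth_i * t), which
is msprime's native growth-rate convention.  Migration is symmetric and
active on the listed windows (rate = per-generation proportion of migrants
in each direction).

Usage: python msprime_backend.py job.json out.txt
"""

import json
import sys

import msprime
import numpy as np


def build_demography(spec):
    dem = msprime.Demography()
    sizes = spec["pop_sizes"]
    growth = spec.get("growth_rates", [0.0, 0.0])
    dem.add_population(name="p1", initial_size=sizes[0], growth_rate=growth[0])
    dem.add_population(name="p2", initial_size=sizes[1], growth_rate=growth[1])
    dem.add_population(name="anc", initial_size=spec["ancestral_size"])
    split_time = spec["split_time"]

    windows = sorted(spec.get("mig_windows", []), key=lambda w: w["start"])
    rate0 = 0.0
    for w in windows:
        if w["start"] <= 0.0 < max(w["end"], 1e-300):
            rate0 = w["rate"]
    if rate0 > 0.0:
        dem.set_symmetric_migration_rate(["p1", "p2"], rate0)
    for w in windows:
        if w["start"] > 0.0 and w["start"] < split_time:
            dem.add_symmetric_migration_rate_change(
                time=w["start"], populations=["p1", "p2"], rate=w["rate"])
        if w["end"] < split_time:
            dem.add_symmetric_migration_rate_change(
                time=w["end"], populations=["p1", "p2"], rate=0.0)
    dem.add_population_split(time=split_time, derived=["p1", "p2"],
                             ancestral="anc")
    dem.sort_events()
    return dem


def simulate_locus(dem, design, anc_seed, mut_seed):
    n = design["n_diploid_per_pop"]
    ts = msprime.sim_ancestry(
        samples={"p1": n, "p2": n},
        demography=dem,
        sequence_length=design["locus_length"],
        recombination_rate=design["recombination_rate"],
        random_seed=anc_seed,
    )
    mu = design["mutation_rate"]
    if mu > 0:
        ts = msprime.sim_mutations(ts, rate=mu, random_seed=mut_seed,
                                   discrete_genome=False)
    G = ts.genotype_matrix()          # sites x haplotypes, 0 = ancestral
    pos = ts.sites_position
    if G.shape[0]:
        # keep biallelic sites segregating in the pooled sample, strictly
        # increasing positions (guards against degenerate collisions)
        counts = G.sum(axis=1)
        keep = (counts > 0) & (counts < G.shape[1]) & (G.max(axis=1) <= 1)
        G, pos = G[keep], pos[keep]
        if len(pos) > 1:
            keep = np.concatenate([[True], np.diff(pos) > 0])
            G, pos = G[keep], pos[keep]
    return G, pos


def maybe_export(ts_like, out_prefix):  # pragma: no cover - optional path
    pass


def main(job_path, out_path):
    with open(job_path) as fh:
        job = json.load(fh)
    design = job["design"]
    with open(out_path, "w") as out:
        for sim in job["sims"]:
            dem = build_demography(sim["demography"])
            for locus in sim["loci"]:
                G, pos = simulate_locus(dem, design,
                                        locus["ancestry_seed"],
                                        locus["mutation_seed"])
                n_hap = 4 * design["n_diploid_per_pop"]
                out.write("L %s %s %d %d\n" %
                          (sim["id"], locus["idx"], n_hap, len(pos)))
                out.write("P " + " ".join("%.6f" % p for p in pos) + "\n")
                GT = G.T  # haplotypes x sites
                if len(pos):
                    arr = GT.astype(np.uint8) + ord("0")
                    for row in arr:
                        out.write(row.tobytes().decode("ascii"))
                        out.write("\n")
                else:
                    for _ in range(n_hap):
                        out.write("\n")


if __name__ == "__main__":
    if len(sys.argv) != 3:
        sys.exit(__doc__)
    main(sys.argv[1], sys.argv[2])
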