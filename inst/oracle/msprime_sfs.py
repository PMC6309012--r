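#!/usr/bin/env python
"""Independent coalescent oracle for the three-deme expected joint SFS.

Reads a JSON spec, simulates with msprime, and writes the mean
branch-length allele-frequency spectrum (and its Monte-Carlo standard
error) per unit mutation rate, flattened in Fortran (column-major) order
to match R arrays.

Spec keys: ns (3 haploid sample sizes), NS, NC, NO, ND, NA (haploid
sizes), TD, TA (years = generations), mS (backward C->S per-lineage
rate), mC (backward S->C), migWindow (0 none, 1 until TD, 2 until TSC),
TSC, nReps, seed.
"""
import json
import sys

import msprime
import numpy as np


def main(spec_path, out_path):
    with open(spec_path) as fh:
        spec = json.load(fh)

    dem = msprime.Demography()
    dem.add_population(name="S", initial_size=spec["NS"])
    dem.add_population(name="C", initial_size=spec["NC"])
    dem.add_population(name="O", initial_size=spec["NO"])
    dem.add_population(name="D", initial_size=spec["ND"])
    dem.add_population(name="A", initial_size=spec["NA"])

    mig_window = spec.get("migWindow", 0)
    if mig_window:
        # msprime migration rates are backwards in time: lineages in
        # `source` jump to `dest`
        dem.set_migration_rate(source="C", dest="S", rate=spec["mS"])
        dem.set_migration_rate(source="S", dest="C", rate=spec["mC"])
        if mig_window == 2:
            tsc = spec["TSC"]
            dem.add_migration_rate_change(time=tsc, source="C", dest="S",
                                          rate=0)
            dem.add_migration_rate_change(time=tsc, source="S", dest="C",
                                          rate=0)
    dem.add_population_split(time=spec["TD"], derived=["S", "C"],
                             ancestral="D")
    dem.add_population_split(time=spec["TA"], derived=["D", "O"],
                             ancestral="A")
    dem.sort_events()

    ns = spec["ns"]
    n_reps = spec["nReps"]
    reps = msprime.sim_ancestry(
        samples={"S": ns[0], "C": ns[1], "O": ns[2]},
        demography=dem, ploidy=1, num_replicates=n_reps,
        random_seed=spec["seed"])

    total = None
    totalsq = None
    for ts in reps:
        sets = [ts.samples(population=p) for p in range(3)]
        afs = ts.allele_frequency_spectrum(
            sample_sets=sets, mode="branch", polarised=True,
            span_normalise=True)
        if total is None:
            total = np.zeros_like(afs)
            totalsq = np.zeros_like(afs)
        total += afs
        totalsq += afs * afs

    mean = total / n_reps
    var = np.maximum(totalsq / n_reps - mean * mean, 0.0)
    se = np.sqrt(var / n_reps)
    out = {
        "dims": list(mean.shape),
        "mean": mean.flatten(order="F").tolist(),
        "se": se.flatten(order="F").tolist(),
        "nReps": n_reps,
    }
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
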