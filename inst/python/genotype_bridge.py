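"""Coalescent completion and mutation overlay for forward-simulated ancestry.

Reads a JSON job description, builds a tskit tree sequence from the forward
simulator's text tables, simplifies to the requested sample individuals,
completes the uncoalesced roots with a randomly mating coalescent
("recapitation", msprime), and overlays mutations by doubling the mutation
rate until a target number of segregating sites is reached, finally
downsampling uniformly to exactly that number.

Job file keys:
  mode            "genotypes" (tables -> per-sample-set genotype CSVs),
                  "recap_only" (tables -> .trees file),
                  "mutate" (.trees -> genotype CSVs),
                  "coal_times" (replicate recapitations, report root times)
  tables          {birth_cycle, edges, final, n_cycles, genome_length}
  recomb_rate     recapitation recombination rate per bp per generation
  epochs          [{"ne": float, "start": int}, ...] backward in time;
                  empty/absent => single epoch with Ne = final census size
  recap_seed      integer seed for recapitation
  sample_sets     [{"individuals": [gid...], "m_target": int, "seed": int,
                    "out": path-prefix}, ...]
  mu_start        starting mutation rate (default 1e-15)
  phased          emit one row per haplotype (0/1) instead of diploid 0/1/2
  trees_out/trees_in  paths for recap_only / mutate modes
  reps            replicate count for coal_times
"""

import json
import sys

import numpy as np
import pandas as pd
import msprime
import tskit


def load_tables(spec):
    birth = pd.read_csv(spec["birth_cycle"], header=None).to_numpy().ravel()
    edges = pd.read_csv(spec["edges"], header=None).to_numpy(dtype=np.float64)
    n_cycles = int(spec["n_cycles"])
    genome_length = float(spec["genome_length"])

    n_ind = birth.shape[0]
    tables = tskit.TableCollection(sequence_length=genome_length)
    tables.populations.add_row()
    time = (n_cycles - birth).astype(np.float64)
    node_time = np.repeat(time, 2)
    n_nodes = 2 * n_ind
    tables.nodes.set_columns(
        flags=np.zeros(n_nodes, dtype=np.uint32),
        time=node_time,
        population=np.zeros(n_nodes, dtype=np.int32),
    )
    if edges.size:
        tables.edges.set_columns(
            left=edges[:, 0].astype(np.float64),
            right=edges[:, 1].astype(np.float64),
            parent=edges[:, 2].astype(np.int32),
            child=edges[:, 3].astype(np.int32),
        )
    return tables


def sample_nodes_for(individuals):
    out = []
    for gid in individuals:
        out.extend([2 * int(gid), 2 * int(gid) + 1])
    return out


def simplified_ts(tables, union_individuals):
    nodes = sample_nodes_for(union_individuals)
    flags = tables.nodes.flags
    flags = np.zeros_like(flags)
    flags[nodes] = tskit.NODE_IS_SAMPLE
    tables.nodes.flags = flags.astype(np.uint32)
    tables.sort()
    tables.simplify(samples=np.array(nodes, dtype=np.int32),
                    keep_input_roots=False)
    # after simplify, sample k of the union maps to node k
    return tables.tree_sequence()


def build_demography(job, default_ne):
    epochs = job.get("epochs") or []
    if not epochs:
        epochs = [{"ne": float(default_ne), "start": 0}]
    dem = msprime.Demography()
    dem.add_population(initial_size=float(epochs[0]["ne"]))
    for ep in epochs[1:]:
        dem.add_population_parameters_change(
            time=float(ep["start"]), initial_size=float(ep["ne"]), population=0)
    return dem


def recapitate(ts, job, default_ne):
    dem = build_demography(job, default_ne)
    return msprime.sim_ancestry(
        initial_state=ts,
        demography=dem,
        recombination_rate=float(job.get("recomb_rate", 0.0)),
        random_seed=int(job.get("recap_seed", 1)),
    )


def segregating(var_genotypes):
    g = var_genotypes
    return 0 < int(np.sum(g > 0)) < g.shape[0]


def overlay_to_target(rts, subset_nodes, m_target, seed, mu_start, max_rounds=60):
    """Add mutations at rate mu_start, doubling the cumulative rate each
    round (by adding an increment equal to the current total), until at
    least m_target sites segregate among subset_nodes; then uniformly
    downsample to exactly m_target sites."""
    rng = np.random.default_rng(seed)
    cur = rts
    total = 0.0
    add = mu_start
    for _ in range(max_rounds):
        cur = msprime.sim_mutations(
            cur, rate=add, random_seed=int(rng.integers(1, 2**31 - 1)),
            discrete_genome=False, keep=True)
        total += add
        add = total
        seg_sites = []
        positions = []
        counts = []
        for var in cur.variants(samples=np.array(subset_nodes, dtype=np.int32)):
            assert len(var.alleles) <= 2, "non-biallelic site under infinite sites"
            if segregating(var.genotypes):
                seg_sites.append(var.site.id)
                positions.append(var.site.position)
                counts.append(var.genotypes.copy())
        if len(seg_sites) >= m_target:
            pick = np.sort(rng.choice(len(seg_sites), size=m_target,
                                      replace=False))
            hap = np.stack([counts[i] for i in pick], axis=1)  # (2n, m)
            pos = np.array([positions[i] for i in pick])
            return hap, pos
    raise RuntimeError("mutation-rate doubling did not reach target SNP count")


def write_sample_set(rts, union_index, sset, mu_start, phased):
    idx = [union_index[int(g)] for g in sset["individuals"]]
    subset_nodes = []
    for k in idx:
        subset_nodes.extend([2 * k, 2 * k + 1])
    hap, pos = overlay_to_target(rts, subset_nodes, int(sset["m_target"]),
                                 int(sset["seed"]), mu_start)
    if phased:
        geno = hap
    else:
        geno = hap[0::2, :] + hap[1::2, :]
    np.savetxt(sset["out"] + "_genotypes.csv", geno, fmt="%d", delimiter=",")
    np.savetxt(sset["out"] + "_positions.csv", pos, fmt="%.6f")


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    mode = job["mode"]
    mu_start = float(job.get("mu_start", 1e-15))
    phased = bool(job.get("phased", False))

    if mode == "mutate":
        rts = tskit.load(job["trees_in"])
        union = job["union_individuals"]
        union_index = {int(g): k for k, g in enumerate(union)}
        for sset in job["sample_sets"]:
            write_sample_set(rts, union_index, sset, mu_start, phased)
        return

    tables = load_tables(job["tables"])
    final = pd.read_csv(job["tables"]["final"], header=None).to_numpy()
    census = final.shape[0]

    if mode == "coal_times":
        union = sorted({int(g) for g in job["union_individuals"]})
        ts = simplified_ts(tables, union)
        times = []
        base = int(job.get("recap_seed", 1))
        for r in range(int(job["reps"])):
            j2 = dict(job)
            j2["recap_seed"] = base + r
            rts = recapitate(ts, j2, census)
            tree = rts.first()
            times.append(max(rts.nodes_time))
        np.savetxt(job["out"], np.array(times))
        return

    union = []
    seen = set()
    for sset in job["sample_sets"]:
        for g in sset["individuals"]:
            g = int(g)
            if g not in seen:
                seen.add(g)
                union.append(g)
    ts = simplified_ts(tables, union)
    n_roots = max(t.num_roots for t in ts.trees())
    rts = recapitate(ts, job, census)
    assert all(t.num_roots == 1 for t in rts.trees())

    if mode == "recap_only":
        rts.dump(job["trees_out"])
        info = {"union_individuals": union, "roots_before": int(n_roots),
                "census": int(census)}
        with open(job["trees_out"] + ".json", "w") as fh:
            json.dump(info, fh)
        return

    union_index = {int(g): k for k, g in enumerate(union)}
    for sset in job["sample_sets"]:
        write_sample_set(rts, union_index, sset, mu_start, phased)


if __name__ == "__main__":
    main(sys.argv[1])
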