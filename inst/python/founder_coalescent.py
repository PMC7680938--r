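"""Coalescent simulation of founder haplotypes for mislabelGS.

Simulates an equilibrium population of effective size Ne with msprime,
one independent tree sequence per chromosome.  Each chromosome is a row
of `segments` loci; recombination happens between but not within
segments (discrete genome, one position = one segment), at the
recombination fraction implied by the uniform genetic map.  Mutations
use a binary (0/1) model at a per-segment rate of mu * segment_bp.

Sites are filtered to minor allele frequency > maf_min among the
sampled haplotypes and written as plain text:

  <out>.sites : TSV with header, columns chrom (1-based), segment (0-based)
  <out>.haps  : one line per retained site; each line is a string of
                0/1 alleles over the 2 * (n_ind + n_backup) sampled
                haplotypes (founders first, then the backup sample; the
                MAF filter is computed on the founders only)

Exit status is non-zero on any error; diagnostics go to stderr.
"""

import argparse
import math
import sys


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--ne", type=float, required=True)
    ap.add_argument("--n-ind", type=int, required=True)
    ap.add_argument("--n-backup", type=int, default=0)
    ap.add_argument("--n-chrom", type=int, required=True)
    ap.add_argument("--segments", type=int, required=True)
    ap.add_argument("--chrom-cm", type=float, required=True)
    ap.add_argument("--segment-bp", type=float, required=True)
    ap.add_argument("--mu", type=float, required=True)
    ap.add_argument("--maf-min", type=float, required=True)
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--out", type=str, required=True)
    args = ap.parse_args()

    import msprime
    import numpy as np

    d_cm = args.chrom_cm / (args.segments - 1)
    # Haldane: map distance between adjacent segments -> recombination fraction
    c = 0.5 * (1.0 - math.exp(-2.0 * d_cm / 100.0))
    mu_seg = args.mu * args.segment_bp

    sites_chrom = []
    sites_seg = []
    hap_lines = []
    base = (args.seed % 1000003) * 1013 + 1
    for chrom in range(args.n_chrom):
        anc_seed = (base + 2 * chrom) % 2147483629 + 1
        mut_seed = (base + 2 * chrom + 1) % 2147483629 + 1
        ts = msprime.sim_ancestry(
            samples=args.n_ind + args.n_backup,
            population_size=args.ne,
            ploidy=2,
            sequence_length=args.segments,
            recombination_rate=c,
            discrete_genome=True,
            random_seed=anc_seed,
        )
        mts = msprime.sim_mutations(
            ts,
            rate=mu_seg,
            model=msprime.BinaryMutationModel(),
            random_seed=mut_seed,
        )
        if mts.num_sites == 0:
            continue
        G = mts.genotype_matrix()  # sites x haplotypes, int8
        # collapse any multiallelic recurrences to presence of derived allele
        G = (G > 0).astype(np.int8)
        # MAF filter on the founder sample only; any extra "shadow
        # germplasm" backup haplotypes are carried along at retained sites
        freq = G[:, : 2 * args.n_ind].mean(axis=1)
        maf = np.minimum(freq, 1.0 - freq)
        keep = (maf > args.maf_min) & (maf < 1.0)
        if not np.any(keep):
            continue
        G = G[keep]
        pos = np.array([s.position for s in mts.sites()])[keep]
        # one site per segment at most: drop duplicated segment positions
        seg = pos.astype(int)
        uniq = np.concatenate(([True], np.diff(seg) > 0))
        G = G[uniq]
        seg = seg[uniq]
        sites_chrom.append(np.full(len(seg), chrom + 1, dtype=int))
        sites_seg.append(seg)
        chars = np.char.mod("%d", G)
        hap_lines.extend("".join(row) for row in chars)

    if not sites_chrom:
        sys.stderr.write("no segregating sites passed the MAF filter\n")
        with open(args.out + ".sites", "w") as fh:
            fh.write("chrom\tsegment\n")
        with open(args.out + ".haps", "w") as fh:
            pass
        return 0

    chrom_all = np.concatenate(sites_chrom)
    seg_all = np.concatenate(sites_seg)
    with open(args.out + ".sites", "w") as fh:
        fh.write("chrom\tsegment\n")
        for ch, sg in zip(chrom_all, seg_all):
            fh.write(f"{ch}\t{sg}\n")
    with open(args.out + ".haps", "w") as fh:
        fh.write("\n".join(hap_lines))
        fh.write("\n")
    return 0


if __name__ == "__main__":
    sys.exit(main())
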