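# hapase

Haplotype-resolved allele-specific analysis of enhancer-hijacking
rearrangements.

## The problem

In B-cell leukaemias carrying an IGH-DUX4 translocation, an oncogene
cassette from a multi-copy paralog family (the DUX4/D4Z4 array) is inserted
next to the IGH intronic enhancer (Eμ). Whether the rearrangement landed on
the transcriptionally **active** or the epigenetically **silenced** IGH
allele changes the biology completely: allelic exclusion means only one
allele carries an active enhancer. Resolving this requires tying every
read — RNA, H3K27ac ChIP, ATAC, bisulfite, Hi-C/HiChIP/Capture-C — to its
haplotype of origin, which in turn requires local haplotype reconstruction
across the breakpoint and careful handling of the near-identical paralog
copies that make the cassette multi-map.

`hapase` implements that analysis as a tested, reusable pipeline for R,
aimed at cancer-genomics and regulatory-genomics analysts:

* **Phasing** — heterozygous SNPs are phased from linked-read barcode
  co-occurrence by greedy minimum error correction (MEC): seed with the
  highest-coverage SNP, extend by descending barcode-sharing weight,
  orient each SNP to minimise contradicted barcode entries. Quality is the
  supporting-minus-contradicting barcode margin.
* **Local assembly support** — barcode recruitment around a target region
  (barcodes with ≥ 20 reads in the region pull in *all* their reads,
  including distal and unmapped mates), a deterministic exact-overlap
  unitig assembler for the clean-read regime, best-match attribution of an
  assembled cassette to its source paralog (identity
  `100 × (L − mismatches)/L`), and reference-linker scaffolding.
* **Allele-specific read-outs** — per-SNP allele counts per assay with the
  exact one-tailed binomial test `p = P(X ≥ n_wt | n, 0.5)`; full-length
  transcript classification (functional Igμ vs antisense oncogene vs sense
  fusion); haplotype-resolved CpG methylation that only uses bisulfite
  reads whose conversion strand leaves the SNP readable (a G/A SNP
  survives only on original-top reads, a C/T SNP only on original-bottom).
* **Contact quantification** — anchor-pair counting with the union rule
  over oncogene array copies, Capture-C peak coverage with viewpoint
  exclusion, multi-mapping rescue (realign family-mapped reads to the
  canonical copy, mismatch-bounded), interaction folds with the
  conventional rounded "N-fold" report, haplotype-aware linear distances,
  and reciprocal-translocation adjacency calls from contact enrichment.
* **Expression** — single-representative-locus counting for multi-copy
  genes, FPKM (`count × 10⁹ / (length × library)`), and paired cohort
  summaries (medians, one-tailed paired *t*, Pearson *r*, ratio CI).

Everything runs end-to-end on a built-in synthetic two-haplotype locus
with known ground truth (`build_genome()` plus simulators for all five
assay types), so the pipeline is fully testable without any external data.

## Worked example

```r
library(hapase)

model <- build_genome(seed = 1)            # two-haplotype locus, T-G-G | A-A-A
lr    <- simulate_linked_reads(model, n_molecules = 400,
                               molecule_len = 3000,
                               reads_per_molecule = 40, seed = 2)
phased <- phase_snps(collect_barcode_allele_matrix(lr$reads, model$snps))
phased
#>   contig snp_id   pos allele_a allele_b hap1_allele phase_set  qual
#> 1 chrL   snp1   15000 A        T        A                   1    19
#> 2 chrL   snp2   16500 A        G        A                   1    36
#> 3 chrL   snp3   17500 A        G        A                   1    23
```

One phase set, haplotypes A-A-A | T-G-G, barcode support margins 19–36.
Now allele-specific expression at a 7.4:1 wild-type bias:

```r
rna <- simulate_tag_reads(model, assay_profile("rna_stranded", depth = 400,
                                               allelic_ratio = 7.4), seed = 3)
imbalance_table(count_alleles(rna$reads, phased, assay = "RNA"))
#>   snp_id assay n_hap1 n_hap2 n_other n_ambiguous  fold      p_value stars
#> 1 snp1   RNA      356     44       0           0  8.09 4.4e-62      ***
#> 2 snp2   RNA      351     49       0           0  7.16 1.1e-57      ***
#> 3 snp3   RNA      365     35       0           0 10.43 1.1e-70      ***
```

Each SNP shows strong wild-type enrichment (folds 7.2–10.4 around the
simulated 7.4) with vanishing one-tailed binomial p-values. The
enhancer-interaction fold from peak coverages 953 (enhancer-promoter) vs
75 (enhancer-oncogene, after multi-mapping rescue):

```r
interaction_fold(953, 75)
#> <interaction_fold> 12.71 (reported as 13-fold)
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages (simulate →
phase → ASE → methylation → contacts → expression) and returns a report
whose qualitative flags summarise the allele-specific picture:
wild-type enrichment in RNA/H3K27ac/ATAC, hypermethylation of the
rearranged haplotype, and a weaker enhancer-cassette interaction despite
its ~35× shorter linear distance. `glance()`, `tidy()` and `autoplot()`
methods are provided for the result objects, and
`inst/scripts/hapase-pipeline.R` wraps the pipeline for shell use.

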