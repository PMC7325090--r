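#!/usr/bin/env Rscript
# Stage 2: single-locus distance screen.
#
# Reads one locus of the deep fixture (stage 1), computes the MEGA-style
# within/between group divergence table under the default settings
# (p-distance, pairwise deletion), calibrates the cutoff from five
# designated reference species, and applies the accept/merge/flag rule.

suppressMessages(library(gcpsr))
dir.create("results", showWarnings = FALSE)

aln <- read_alignment("scratch/fixture_deep/aln_001.fasta")
part <- read_partition("scratch/fixture_deep/partition.tsv")
aln <- aln[rownames(aln) %in% names(part), , drop = FALSE]
class(aln) <- c("seq_alignment", class(aln))

dt <- group_divergence(aln, part)
refs <- sort(names(partition_groups(part)))[1:5]
cut <- calibrate_cutoff(dt, refs)
dec <- decide_species(dt, cut$cutoff)

tab <- rbind(
  data.frame(kind = "within", group = dt$within$group, other = NA,
             mean_pct = round(100 * dt$within$mean, 3),
             n_pairs = dt$within$n_pairs),
  data.frame(kind = "between", group = dt$between$group1,
             other = dt$between$group2,
             mean_pct = round(100 * dt$between$mean, 3),
             n_pairs = dt$between$n_pairs))
write.table(tab, "results/02_divergence_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(dec, "results/02_species_decisions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Cutoff: %.3f%% (from reference group %s)\n",
            100 * cut$cutoff, cut$source_group))
cat(sprintf("Accepted %d of %d groups; %d flagged as multiple species.\n",
            sum(dec$status == "accepted"), nrow(dec),
            sum(dec$flagged_multiple)))
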