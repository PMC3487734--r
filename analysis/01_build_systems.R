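#!/usr/bin/env Rscript
# Stage 1: construct every synthetic system the downstream analyses use --
# the wild-type and S20G 1-25 peptides as ideal helices (helical span 5-25,
# disordered N-terminal loop), the DOPC/DOPS slab pseudo-bilayer with water
# and neutralising counterions, and the default membrane-embedded peptide
# (helix parallel to the surface, centre 7 A below the phosphate plane,
# Thr9/Leu12/Leu16/Ser20 facing the core).
#
# Small structures go to results/systems; the full solvated bilayer PDB is
# bulky scratch output.

suppressMessages(library(memhelix))
dir.create("results/systems", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch", showWarnings = FALSE)

wt <- build_ideal_helix()
mut <- build_ideal_helix(s20g = TRUE)
write_structure(wt, "results/systems/iapp1_25_wt_helix.pdb")
write_structure(mut, "results/systems/iapp1_25_s20g_helix.pdb")
cat(sprintf("peptides: WT %d atoms, S20G %d atoms (Gly20 drops the side-chain bead)\n",
            nrow(wt$atoms), nrow(mut$atoms)))

spec <- slab_bilayer_spec()          # 88 DOPC + 40 DOPS, A_L 64 A^2, D 38 A
bl <- build_slab_bilayer(spec)
n_ions <- neutralize(spec$counts, spec$charges)
bl_ion <- add_counterions(bl, n_ions, seed = spec$seed)
cat(sprintf("bilayer: %d atoms; %d Na+ added to neutralise %d DOPS\n",
            nrow(bl_ion$atoms), n_ions, spec$counts[["DOPS"]]))
write_structure(bl_ion, "scratch/bilayer_solvated.pdb")

emb <- embed_peptide(bl, wt, embed_spec())
cat(sprintf("embedding removed %d clashing lipids\n",
            attr(emb, "removed_lipids")))
write_structure(emb, "scratch/embedded_wt.pdb")

depth <- immersion_depth(emb, select_atoms(emb, "phosphorus"), "upper",
                         selection = select_atoms(
                           emb, "chain A and resid 5:25 and name CA"))
cat(sprintf("helix-centre immersion depth of the embedded build: %.2f A\n",
            depth))

write_tsv_report(
  data.frame(species = c(names(spec$counts), "Na+"),
             count = c(unname(spec$counts), n_ions),
             charge = c(unname(spec$charges[names(spec$counts)]), +1)),
  "results/systems/composition.tsv",
  params = list(area_per_lipid_A2 = spec$area_per_lipid,
                p_separation_A = spec$p_separation,
                box_z_A = spec$box_z, seed = spec$seed))
cat("wrote results/systems/composition.tsv\n")
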