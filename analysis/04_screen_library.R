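#!/usr/bin/env Rscript
# Step 4: the full chemistry path on a small pesticide library.
# SMILES in, deterministic conformer ensembles, feature perception, a
# ligand-based model built by merging the features of a training
# compound's conformers, screening with union-of-models semantics, and a
# cross-reference of the hits against a reference identifier list (the
# stand-in for a metabolome inventory lookup).

suppressMessages(library(pharmscreen))
dir.create("results", showWarnings = FALSE)

pesticides <- c(
  atrazine      = "CCNc1nc(Cl)nc(NC(C)C)n1",
  cyanazine     = "CCNc1nc(Cl)nc(NC(C)(C)C#N)n1",
  terbutryn     = "CCNc1nc(NC(C)(C)C)nc(SC)n1",
  bupirimate    = "CCCCc1c(C)nc(NCC)nc1OS(=O)(=O)N(C)C",
  pymetrozine   = "Cc1cnn(C(=O)N2CCN(C)CC2)c1",   # synthetic analog scaffold
  phenmedipham  = "CNC(=O)Oc1cccc(NC(=O)Oc2cccc(C)c2)c1",
  boscalid      = "Clc1ccc(-c2ccccc2NC(=O)c2cccnc2Cl)cc1")

tf <- tempfile(fileext = ".smi")
writeLines(paste(pesticides, names(pesticides), sep = "\t"), tf)
library_records <- read_smiles_table(tf)
library_mols <- lapply(library_records, function(r)
  generate_conformers(r$molecule, max_conformers = 20,
                      seed = derive_seed(20250924, r$molecule$id)))
cat(sprintf("embedded %d molecules, %s conformers each\n",
            length(library_mols),
            paste(range(vapply(library_mols, function(m)
              length(m$conformers), integer(1))), collapse = "-")))

# ligand-based model from two conformers of atrazine (pre-aligned by
# matching both feature sets in the same frame is unnecessary here:
# features of conformer 1 are used as the common frame via self-merge)
atz <- library_mols[[which(vapply(library_mols, `[[`, "", "id") == "atrazine")]]
fs1 <- perceive_features(atz, 1)
model <- build_ligand_based_model(list(fs1, fs1), merge_radius = 1.0,
                                  min_fraction = 1.0, id = "TRIAZINE_LB1",
                                  target = "other", radius = 1.5)
col <- model_collection(c(load_models(exemplar_model_path())$models,
                          list(model)))

screen <- screen_library(col, library_mols)
hits <- screen_hits(screen)

# reference list mixing structure keys and plain names
keys <- vapply(library_mols, `[[`, "", "structure_key")
names(keys) <- vapply(library_mols, `[[`, "", "id")
reference <- c(unname(keys["cyanazine"]), "Atrazine", "boscalid")
annotated <- cross_reference(hits, reference, structure_keys = keys)

write.table(annotated, "results/screen_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
census <- hit_census(screen)
cat(sprintf("hits: %d unique molecule(s) across targets; %d in reference list\n",
            census$overall,
            unname(attr(annotated, "summary")["n_in_reference"])))
print(annotated)
cat("wrote results/screen_hits.tsv\n")
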