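# Hand-traced 30-record curation fixture. The expected funnel was
# traced by hand from the rules:
#   input 30
#   -> length filter (>= 200 aa)                     25  (r01-r05 at 150 aa out)
#   -> homology hit (bit > 20 AND cols >= 30)        20  (r26 bit 20.0, r27 cols 29,
#                                                         r28-r30 no hit)
#   -> CD-HIT representative (longest per cluster)   19  (r07 loses to r06)
#   -> cap 5 per (AP cluster, allowed annotation)    14  (A1 keeps 5 of 8 tail spikes,
#                                                         A2 keeps 5 of 6 tail fibers,
#                                                         A3 keeps 4; r25 disallowed)
#   -> structure hit (p > 0.5; beta-helix p > 0.2)    9
curation_fixture <- function(dir = tempfile("curation")) {
  dir.create(dir)
  lens <- c(r01 = 150L, r02 = 150L, r03 = 150L, r04 = 150L, r05 = 150L,
            r06 = 300L, r07 = 250L, r08 = 290L, r09 = 280L, r10 = 270L,
            r11 = 260L, r12 = 255L, r13 = 310L, r14 = 305L, r15 = 300L,
            r16 = 295L, r17 = 290L, r18 = 285L, r19 = 240L, r20 = 230L,
            r21 = 220L, r22 = 221L, r23 = 222L, r24 = 223L, r25 = 320L,
            r26 = 400L, r27 = 410L, r28 = 420L, r29 = 430L, r30 = 440L)
  ann <- rep("tail spike", 30)
  names(ann) <- names(lens)
  ann[c("r13", "r14", "r15", "r16", "r17", "r18")] <- "tail fiber"
  ann["r25"] <- "terminase large subunit"
  records <- lapply(names(lens), function(id)
    flat_record(id, lens[[id]], ann[[id]]))
  fasta <- file.path(dir, "records.fasta")
  write_fasta(records, fasta)

  hom <- c(
    sprintf("%s\tPDdb_entry1\t25.0\t40\t10\t60", sprintf("r%02d", 6:25)),
    "r26\tPDdb_entry1\t20.0\t100\t10\t120",
    "r27\tPDdb_entry2\t500\t29\t10\t40")
  hom_path <- file.path(dir, "homology.tsv")
  writeLines(hom, hom_path)

  clstr <- c(">Cluster 0",
             "0\t300aa, >r06... *",
             "1\t250aa, >r07... at 96.2%")
  singletons <- setdiff(names(lens), c("r06", "r07"))
  for (i in seq_along(singletons)) {
    clstr <- c(clstr, sprintf(">Cluster %d", i),
               sprintf("0\t%daa, >%s... *", lens[[singletons[i]]],
                       singletons[i]))
  }
  clstr_path <- file.path(dir, "clusters.clstr")
  writeLines(clstr, clstr_path)

  ap <- c(r06 = "A1", r08 = "A1", r09 = "A1", r10 = "A1", r11 = "A1",
          r12 = "A1", r19 = "A1", r20 = "A1",
          r13 = "A2", r14 = "A2", r15 = "A2", r16 = "A2", r17 = "A2",
          r18 = "A2",
          r21 = "A3", r22 = "A3", r23 = "A3", r24 = "A3", r25 = "A3")
  # cover the remaining ids so the cap's cluster-coverage pre holds
  rest <- setdiff(names(lens), names(ap))
  ap[rest] <- paste0("S_", rest)
  ap_path <- file.path(dir, "ap_clusters.tsv")
  writeLines(paste(names(ap), ap, sep = "\t"), ap_path)

  struct <- c(
    "r06\tbhelix_ref\t0.25\t50\t200",
    "r08\tbhelix_ref\t0.20\t50\t200",
    "r09\tpropeller_ref\t0.51\t40\t220",
    "r10\ttoroid_ref\t0.50\t40\t220",
    "r11\tbhelix_ref\t0.92\t30\t230",
    "r13\tpropeller_ref\t0.60\t50\t250",
    "r14\tbhelix_ref\t0.21\t50\t250",
    "r15\ttim_ref\t0.55\t50\t250",
    "r16\tbhelix_ref\t0.15\t50\t250",
    "r17\tflavodoxin_ref\t0.40\t50\t250",
    "r21\tpropeller_ref\t0.90\t20\t200",
    "r22\tbhelix_ref\t0.95\t20\t200",
    "r23\ttoroid_ref\t0.51\t20\t200",
    "r07\tbhelix_ref\t0.90\t20\t200")
  struct_path <- file.path(dir, "structure.tsv")
  writeLines(struct, struct_path)

  fold_map <- c(bhelix_ref = "BETA_HELIX",
                propeller_ref = "BETA_PROPELLER",
                toroid_ref = "TOROID",
                tim_ref = "TIM_BARREL",
                flavodoxin_ref = "FLAVODOXIN_LIKE")
  fold_map_path <- file.path(dir, "fold_map.yaml")
  yaml::write_yaml(as.list(fold_map), fold_map_path)

  ann_path <- file.path(dir, "annotations.txt")
  writeLines(c("tail spike", "tail fiber"), ann_path)

  list(dir = dir, fasta = fasta, homology = hom_path,
       clstr = clstr_path, ap_clusters = ap_path,
       structure = struct_path, fold_map = fold_map,
       fold_map_path = fold_map_path, annotations = ann_path,
       expected_funnel = c(input = 30L, length_filter = 25L,
                           homology_hit = 20L,
                           cluster_representative = 19L,
                           annotation_cap = 14L,
                           structure_confirmed = 9L),
       expected_curated = c("r06", "r09", "r11", "r13", "r14", "r15",
                            "r21", "r22", "r23"))
}
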