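# Shared simulated worlds, built once per test run.
.world_cache <- new.env(parent = emptyenv())

# The default-scale world (the study conditions) used by the acceptance tests.
default_world <- function() {
  if (is.null(.world_cache$default)) {
    w <- simulate_world(sim_config(seed = 42),
                        out_dir = file.path(tempdir(), "sc_world_default"))
    .world_cache$default <- c(list(world = w), load_world(w))
  }
  .world_cache$default
}

# A small world for cheap unit tests of the pipeline plumbing.
small_world <- function() {
  if (is.null(.world_cache$small)) {
    cfg <- sim_config(seed = 9L, genome_length = 300000L, chry_length = 40000L,
                      n_genes = 8L, n_chry_genes = 1L, n_targets = 6L,
                      n_close = 2L, intergenic = c(2000L, 5000L))
    w <- simulate_world(cfg, out_dir = file.path(tempdir(), "sc_world_small"))
    .world_cache$small <- c(list(world = w), load_world(w))
  }
  .world_cache$small
}

# Feature vectors over the default world (computed once; reused by the
# classifier and acceptance tests).
default_features <- function() {
  if (is.null(.world_cache$features)) {
    d <- default_world()
    mane <- apply_exclusions(d$mane, "chrY")
    cat_ <- apply_exclusions(d$catalog, "chrY")
    mst <- extract_sites(mane, d$ref)
    st <- extract_sites(cat_, d$ref)
    all_origins <- rbind(st$donors[, c("contig", "origin")],
                         st$acceptors[, c("contig", "origin")])
    rc <- random_config(n_transcripts = 1000L, seed = 17L)
    rnd <- generate_random_annotation(
      eligible_regions(mst$introns, all_origins, rc), d$ref, rc)
    .world_cache$features <- list(
      mane_sites = mst, cat_sites = st, random = rnd, rc = rc,
      fv = list(
        mane_donor = feature_vectors(mst$donors, d$aln, d$ref, d$targets),
        mane_acceptor = feature_vectors(mst$acceptors, d$aln, d$ref, d$targets),
        rnd_donor = feature_vectors(rnd$donors, d$aln, d$ref, d$targets),
        rnd_acceptor = feature_vectors(rnd$acceptors, d$aln, d$ref, d$targets),
        cat_donor = feature_vectors(st$donors, d$aln, d$ref, d$targets),
        cat_acceptor = feature_vectors(st$acceptors, d$aln, d$ref, d$targets)))
  }
  .world_cache$features
}
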