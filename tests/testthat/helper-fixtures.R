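# shared fixtures, built in code

# one-target score table with chosen active/decoy scores
screen_table <- function(active_scores, decoy_scores, target = "T") {
  data.frame(
    target_id = target,
    ligand_id = sprintf("%s_l%02d", target,
                        seq_len(length(active_scores) +
                                  length(decoy_scores))),
    role = c(rep("active", length(active_scores)),
             rep("decoy", length(decoy_scores))),
    dg_pred = c(active_scores, decoy_scores),
    stringsAsFactors = FALSE)
}

# multi-target table with per-target planted top-7 hit counts: k actives
# rank in the top 7 by construction
planted_k_table <- function(ks, n_active = 15, n_decoy = 20, n_top = 7) {
  do.call(rbind, lapply(seq_along(ks), function(t) {
    k <- ks[t]
    act <- c(seq(-20, by = 0.5, length.out = k),        # top-ranked
             seq(-8, by = 0.1, length.out = n_active - k))
    dec <- c(seq(-19.9, by = 0.5, length.out = n_top - k),
             seq(-9, by = 0.1, length.out = n_decoy - (n_top - k)))
    screen_table(act, dec, target = sprintf("T%02d", t))
  }))
}

# brute-force per-ligand-atom protein contact counts (descriptor oracle)
brute_contacts <- function(cx, cutoff) {
  lig <- cx$ligand[!cx$ligand$element %in% c("H", "D"), ]
  prot <- cx$protein[!cx$protein$element %in% c("H", "D"), ]
  vapply(seq_len(nrow(lig)), function(i) {
    d2 <- (prot$x - lig$x[i])^2 + (prot$y - lig$y[i])^2 +
      (prot$z - lig$z[i])^2
    sum(sqrt(d2) <= cutoff)
  }, numeric(1))
}

write_pdb_fixture <- function(...) {
  f <- tempfile(fileext = ".pdb")
  simulate_complex_geometry(..., path = f)
  f
}
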