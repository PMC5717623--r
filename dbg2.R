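library(gesturenet)
pop <- generate_population(synthetic_config(seed = 3, overlap_core = 0, individual_type_mode = "disjoint"))
pr <- pop$repertoires$present
sh <- tcrossprod(pr*1); diag(sh) <- 0
cat("shared (tcrossprod) sum:", sum(sh), "\n")

ds <- generate_dataset(synthetic_config(seed = 71, n_follows = 36))
g <- group_sequences(ds$gestures)
g <- suppressMessages(assign_panthoot_recipients(g, ds$scans, dominance_order(ds$individuals)))
reps <- build_repertoires(g, adults = ds$individuals$id, catalog = ds$catalog)
st <- sequence_homogeneity_table(g, reps)
print(summary(st[, c("homog_size","heterog_size","response_present")]))
print(table(st$response_present))
spec <- glmm_spec("response_present", c("homog_size","heterog_size"), "signaller_id", "binomial_logit")
res <- try(fit_glmm(st, spec))
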