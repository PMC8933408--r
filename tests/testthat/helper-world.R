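# Shared small-scale synthetic world, built once per test run.
# 120 scenes / 10 sources / 15 electrodes / 50-dim embedding keeps every
# decoding test fast while leaving enough signal for recovery checks.

make_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    vocab <- synthetic_vocabulary(embedding_dim = 50)
    emb <- make_embedding(vocab, seed = 1)
    stim <- make_annotated_stimuli(120, emb, vocab, seed = 2, n_sources = 10)
    subj <- subject_model(n_electrodes = 15, d_semantic = 50,
                          noise_sd = 0.05, seed = 3)
    sim <- simulate_watching_features(stim, subj, seed = 4)
    plan <- plan_scene_groups(stim$source_of_scene, k = 10)
    cats <- category_vectors(emb)
    pca <- fit_pca(stim$V_true)
    final <- fit_final_decoder(sim$features, stim$V_true, plan,
                               grid = 10^seq(-4, 4))
    pool <- image_pool(stim$scene_ids, stim$V_true)
    cache <<- list(vocab = vocab, emb = emb, stim = stim, subj = subj,
                   sim = sim, plan = plan, cats = cats, pca = pca,
                   final = final, pool = pool)
    cache
  }
})

# Null subject: feature stream carries no target or feedback information.
make_null_subject <- function(noise_sd = 0.05) {
  subject_model(n_electrodes = 15, d_semantic = 50, noise_sd = noise_sd,
                imagery_gain = 0, attention_gain = 0, seed = 3)
}
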