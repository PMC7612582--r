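qnmodel "FRC_metabolism"
note "Reconstruction of an executable model of FRC central carbon metabolism"
note "with an in-silico mitochondrial stress test readout (OCR, 0-10)."
note "H_in encodes proton concentration: a HIGH level means LOW pH."
node Ext_Lactate range 0 4 target default desc "extracellular lactate load; environment node (2 = normal)"
node Ext_Protons range 0 4 target default desc "extracellular proton load; environment node (2 = neutral pH)"
node MCT1 range 0 4 target default desc "monocarboxylate transporter 1 activity, induced by lactate"
node Int_Lactate range 0 4 target default desc "intracellular lactate, imported via MCT1"
node H_in range 0 4 target default desc "intracellular proton concentration (high = acidic); protons enter with MCT1-borne lactate only under extracellular acid load"
node Glycolysis range 0 4 target "4 - H_in" desc "glycolytic flux, inhibited by cytosolic acidification"
node Pyruvate range 0 4 target "ceil(avg(Glycolysis, Int_Lactate))" desc "pyruvate pool fed by glycolysis and imported lactate"
node AcetylCoA range 0 4 target default desc "acetyl-CoA produced from pyruvate"
node TCA_flux range 0 4 target "min(AcetylCoA, 5 - H_in, 2)" desc "TCA cycle flux: substrate-limited, acid-inhibited, ADP-capped at normal"
node Acetylcarnitine range 0 4 target "AcetylCoA - TCA_flux + 2" desc "acetylcarnitine shunt: sink for acetyl-CoA exceeding TCA entry"
node NADH range 0 4 target default desc "reducing equivalents delivered to the chain"
node ETC range 0 4 target "min(NADH + Uncoupling, 5 - ProtonGradient + Uncoupling) * (1 - RotAA)" desc "electron transport chain (complexes I-IV): NADH-driven, gradient-throttled, uncoupling-relieved, ablated by rotenone/antimycin A"
node ProtonGradient range 0 4 target "2 * ETC + 2 - 2 * ATP_Synthase - 3 * Uncoupling" desc "inner-membrane proton-motive force: built by the chain, dissipated by ATP synthase and uncoupling"
node ATP_Synthase range 0 4 target "2 * (1 - Oligomycin)" desc "ATP synthase activity, shut off by oligomycin"
node Uncoupling range 0 4 target "4 * FCCP" desc "proton permeability of the inner membrane, driven to maximum by FCCP"
node ATP range 0 4 target default desc "cellular ATP supply from oxidative and glycolytic routes"
node OCR range 0 10 target "ceil(5 * ETC / 2)" desc "oxygen consumption rate readout, chain activity scaled to 0-10"
node Counter range 0 100 target "Counter + 1" desc "assay clock: one unit per step, roughly one minute"
node Oligomycin range 0 1 target default desc "drug switch: ATP synthase inhibitor (set by the protocol only)"
node FCCP range 0 1 target default desc "drug switch: protonophore uncoupler (set by the protocol only)"
node RotAA range 0 1 target default desc "drug switch: rotenone + antimycin A (set by the protocol only)"
edge Ext_Lactate -> MCT1 activator
edge MCT1 -> Int_Lactate activator
edge Ext_Lactate -> Int_Lactate activator
edge Ext_Protons -> H_in activator
edge H_in -> Glycolysis inhibitor
edge Glycolysis -> Pyruvate activator
edge Int_Lactate -> Pyruvate activator
edge Pyruvate -> AcetylCoA activator
edge AcetylCoA -> TCA_flux activator
edge H_in -> TCA_flux inhibitor
edge AcetylCoA -> Acetylcarnitine activator
edge TCA_flux -> Acetylcarnitine inhibitor
edge TCA_flux -> NADH activator
edge NADH -> ETC activator
edge ProtonGradient -> ETC inhibitor
edge Uncoupling -> ETC activator
edge RotAA -> ETC inhibitor
edge ETC -> ProtonGradient activator
edge ATP_Synthase -> ProtonGradient inhibitor
edge Uncoupling -> ProtonGradient inhibitor
edge Oligomycin -> ATP_Synthase inhibitor
edge FCCP -> Uncoupling activator
edge ATP_Synthase -> ATP activator
edge Glycolysis -> ATP activator
edge ETC -> OCR activator
edge Counter -> Counter activator
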