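{"description":"synthetic 6-mode bundle with planted resonances (generateBundle, seed 2026)","plan":{"nModes":6,"omegaRange":[300,1700],"minSpacing":8,"cubicScale":10,"quarticScale":5,"backgroundDensity":0.15,"propertyScale":0.05,"seed":2026},"planted":[{"kind":"FERMI_I","i":4,"j":1,"k":1,"delta":2.6,"coupling":38},{"kind":"DD11","i":2,"j":3,"delta":-4.5,"coupling":20}]}
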