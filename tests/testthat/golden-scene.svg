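<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="124.74" height="66" viewBox="0 0 124.74 66">
<rect x="10" y="10" width="20" height="20" fill="#99e" stroke="#000" stroke-width="0.5"/>
<polygon points="20,10 30,20 20,30 10,20" fill="#9ce"/>
<rect x="32" y="10" width="20" height="20" fill="#fff" stroke="#000" stroke-width="0.5"/>
<polygon points="42,10 52,20 42,30 32,20" fill="#ccc"/>
<text x="42" y="23.3" font-family="Helvetica" font-size="8.8" text-anchor="middle" fill="#333">30</text>
<rect x="32" y="36" width="20" height="20" fill="#99e" stroke="#000" stroke-width="0.5"/>
<polygon points="42,36 52,46 42,56 32,46" fill="#9ce"/>
<text x="67" y="23.85" font-family="Helvetica" font-size="11">strainA</text>
<text x="67" y="49.85" font-family="Helvetica" font-size="11">strainB</text>
</svg>
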