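set_name	dog
mcb	Annsown Sir Gay
mcb	Beltore Bright Star
mcb	Lowmont Lady Cadette
mcb	Canorwoll of Thee I Sing
mcb	Carillon Michelle
mcb	Robin Hill of Carillon
mcb	Petitcote Domino
mcb	Petitcote Bubbling Over
mcb	Clairedge Cinderella
mcb	Bel Tor Hosanna
wycliffe	Sedberght Mitzi
wycliffe	Annsown Gay Knight
wycliffe	Petticote Domino
wycliffe	Carrillon Michelle
wycliffe	Carillon Dilemma
oea	Vulcan Golden Light
oea	Alpenden Owstonferry Golden Orial
oea	Pinetum Shantung Tatters
oea	Frenches the Golden Horn
oea	Tangerine of Whittens
oea	Vulcan Merry Sonatina
oea	Vulcan Champagne Tansy
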